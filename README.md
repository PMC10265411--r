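# acenet

Disclosure classification and egocentric network analysis of adverse
childhood experiences (ACEs) on social media.

Adverse childhood experiences — abuse, neglect, and household challenges in
the first 17 years of life — are common and carry lifelong health
consequences; social connectedness is one of the main mitigating factors.
acenet is for digital-epidemiology researchers who want to study how people
who publicly disclose ACEs are embedded in web-based social networks. It
implements the full analysis chain as tested, offline-runnable R:

1. **Text preprocessing** — cleaning short posts into token sequences,
   eligibility filtering (more than 5 words after cleaning), and keyword
   queries with OR / AND / AND-NOT semantics for sampling user groups.
2. **Mention scoring** — a seeded embedding + convolution + max-pool
   softmax classifier (implemented in vectorized base R, no deep-learning
   framework needed) whose output in [0, 1] is the *ACE mention score* of a
   text, with balanced subsampling, a stratified 72/8/20 split, strict
   0.5-threshold classification and the five standard performance measures
   (accuracy, precision, recall, F1, AUC).
3. **User scoring** — the *ACE alignment index* α of a user: the top-10%
   value (the ⌈0.1 n⌉-th largest) of the mention scores of their ≥ 30
   eligible texts. α ≥ 0.5 makes a user ACE; all scores < 0.3 makes them
   non-ACE.
4. **Sentiment profiling** — thresholds s ≤ −0.05 / s ≥ 0.05 around a
   pluggable scorer in [−1, 1].
5. **Egocentric network indexes** — on sampled directed follow networks
   (≤ 100 followers/followees per root): reciprocity r1 = reciprocal
   neighbors / m1 and r2 (per followees), strict and weak restricted local
   clustering C1, C1′, C2, C2′ over reciprocal-neighbor pairs, homophily
   averages ⟨α⟩_follower / ⟨α⟩_followee, reciprocal-vs-nonreciprocal
   follower contrasts, and degree survival curves.
6. **Group comparison** — two-sided Mann-Whitney-Wilcoxon tests over the
   three group pairs (ACE, non-ACE-1, non-ACE-2) with Bonferroni
   correction (×3, capped at 1).
7. **Synthetic data** — generators with planted follow-back probability,
   triangle density, homophily and per-user score structure, so every
   stage is testable without any platform access.

## Worked example

Score a user and compare planted network effects across groups:

```r
library(acenet)

# 30 eligible texts, 4 of them scoring high: the top-10% value (3rd
# largest of 30) is 0.85, so the user is categorized as ACE
scores <- c(rep(0.85, 4), rep(0.12, 26))
alignment_index(scores)   # 0.85
categorize_user(scores)   # "ACE"

# an egocentric-network study with group differences planted in the
# follow-back probability and homophily only
specs <- list(
  ACE       = ego_net_spec(p_back = 0.45, h = 0.8),
  NON_ACE_1 = ego_net_spec(p_back = 0.35, h = 0.6),
  NON_ACE_2 = ego_net_spec(p_back = 0.25, h = 0.6))
study <- generate_ego_study(
  n_roots = c(ACE = 80L, NON_ACE_1 = 80L, NON_ACE_2 = 80L),
  specs = specs, seed = 42)
compare_groups(study$r1, study$group, "r1")
```

```
Group comparison: r1

     group  n      mean         sd    median
       ACE 80 0.4538377 0.06140887 0.4516667
 NON_ACE_1 80 0.3395640 0.06550760 0.3400000
 NON_ACE_2 80 0.2404138 0.05730132 0.2500000

Pairwise two-sided rank-sum tests (Bonferroni m = 3):
   group_a   group_b statistic        p_raw p_bonferroni
       ACE NON_ACE_1    5901.0 2.983093e-20 8.949280e-20
       ACE NON_ACE_2    6388.5 1.396238e-27 4.188714e-27
 NON_ACE_1 NON_ACE_2    5795.5 7.903020e-19 2.370906e-18
```

The per-group mean r1 recovers each planted follow-back probability
(0.45 / 0.35 / 0.25), and all three pairwise differences are significant
after correction. Replacing `r1` with `avg_alpha_follower` shows the
homophily signal: ACE roots' followers average a far higher alignment index
(0.72) than the non-ACE groups' (0.50 / 0.47).

A command-line interface wrapping the same functions lives in
`exec/acenet` (subcommands `clean`, `match`, `train`, `score`, `users`,
`egonet`, `compare`); see the file header for usage.

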