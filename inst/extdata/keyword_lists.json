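{
  "parent_guardian": ["my mother", "my father", "my mom", "my dad", "my guardian"],
  "parent": ["my mother", "my father", "my mom", "my dad"],
  "everyday": ["school", "basketball", "game", "dog", "cosplay", "shopping"],
  "s": ["abuse", "neglect", "jail", "prison", "substance use",
        "substance misuse", "substance abuse", "overdose", "od",
        "drug addiction", "parental separation", "divorce"]
}
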