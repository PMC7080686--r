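{
  "hba1c": ["83036", "83037"],
  "ldl": ["80061", "83721"],
  "retinal_exam": ["92250", "S0625"],
  "mammography": ["77067", "77063"]
}
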