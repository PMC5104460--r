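.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".GRP", "uid", "gameplay", "ci", "ti", "gp", "cell", "condition",
  "guess_stage", "chosen_row", "first_card", "sample1_value", "sample2_row",
  "sample2_value", "trial_type", "d_opt", "rel", "mean_relative",
  "mean_relative_1", "mean_relative_2", "num", "den", "dir", "act", "c_eff",
  "is_aa", "block", "trial", "policy", "c1", "c2", "b1", "b2", "b3", "b4",
  "b5", "b6", "tau"))
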