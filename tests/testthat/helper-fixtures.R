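# Shared fixtures: loading the bundled study tables once per test run, and a
# small noise-free synthetic configuration used by the recovery tests.
soil_tbl <- load_concentration_table(gt_example("table1_soil.csv"))
plant_tbl <- load_concentration_table(gt_example("table2_plant.csv"))
bev_tbl <- load_concentration_table(gt_example("table3_must_wine.csv"))

noise_free_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, cv_noise = 0,
                   loq = stats::setNames(rep(0, 9), gt_elements()), ...)
}

# mean of the printed per-variety mobility ratios for a pair x element
mr_fixture <- utils::read.csv(gt_example("table6_mr.csv"),
                              stringsAsFactors = FALSE)
tf_fixture <- utils::read.csv(gt_example("table5_tf.csv"),
                              stringsAsFactors = FALSE)
mr_values <- function(pair, element)
  mr_fixture$ratio[mr_fixture$pair == pair & mr_fixture$element == element]
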