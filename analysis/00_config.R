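# Shared configuration of the analysis scripts. The assay protocol runs
# 20-minute trials (10 min habituation + 10 min observation) with 10
# subjects per condition; these drivers use a reduced-scale study (2 min
# habituation-trimmed observation, 6 subjects) so the whole sequence runs
# in about a minute — the package defaults keep the full protocol values.
library(roboshoal)

study_config <- function() {
  experiment_config(habituation_s = 30, observation_s = 120,
                    trials_per_condition = 6, seed = 20160505)
}

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)
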