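# Statistical battery over the study tables written by script 03:
# one-sample t-tests of both preference indices against chance, one-way
# ANOVAs across conditions with Tukey HSD post hoc tests where warranted,
# and the direction x segment ANOVA of normalized transfer entropy per
# condition.
source("analysis/00_config.R")

trials <- read.csv(file.path(results_dir, "trials.csv"))
kept <- trials[!trials$excluded, ]

t_rows <- do.call(rbind, lapply(split(kept, kept$condition), function(d) {
  do.call(rbind, lapply(c("PI_stimulus", "PI_bottom"), function(v) {
    vals <- d[[v]][is.finite(d[[v]])]
    if (length(vals) < 2 || sd(vals) == 0) return(NULL)
    tt <- one_sample_t(vals, mu0 = 0.5, tail = "greater")
    data.frame(condition = d$condition[1], observable = v,
               t = tt$statistic, df = tt$df, p_one = tt$p,
               p_two = tt$p_two_sided)
  }))
}))
cat("one-sample t-tests vs chance (0.5):\n")
print(t_rows, digits = 3, row.names = FALSE)

anova_rows <- NULL
for (v in c("PI_stimulus", "PI_bottom", "T_mid_len", "T_mid_depth",
            "mean_speed", "mean_accel", "shoaling_s")) {
  gr <- lapply(split(kept[[v]], kept$condition), function(x) x[is.finite(x)])
  gr <- gr[lengths(gr) >= 2]
  if (length(gr) < 2) next
  a <- one_way_anova(gr)
  anova_rows <- rbind(anova_rows, data.frame(
    observable = v, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p))
  if (a$p < 0.05) {
    cat(sprintf("\nTukey HSD for %s (ANOVA p = %.4f):\n", v, a$p))
    print(round(tukey_hsd(gr), 4))
  }
}
cat("\nbetween-condition one-way ANOVA:\n")
print(anova_rows, digits = 3, row.names = FALSE)

te_path <- file.path(results_dir, "te_long.csv")
te_anova <- NULL
if (file.exists(te_path)) {
  te_long <- read.csv(te_path)
  te_anova <- do.call(rbind, lapply(split(te_long, te_long$condition),
                                    function(d) {
    if (length(unique(d$segment)) < 2) return(NULL)
    res <- tryCatch(direction_segment_anova(d), error = function(e) {
      cat(sprintf("condition %s: %s\n", d$condition[1], conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    cbind(condition = d$condition[1], res)
  }))
  cat("\ndirection x segment ANOVA of normalized transfer entropy:\n")
  print(te_anova, digits = 3, row.names = FALSE)
}

write.csv(t_rows, file.path(results_dir, "stats_t_tests.csv"),
          row.names = FALSE)
write.csv(anova_rows, file.path(results_dir, "stats_anova.csv"),
          row.names = FALSE)
if (!is.null(te_anova))
  write.csv(te_anova, file.path(results_dir, "stats_te_anova.csv"),
            row.names = FALSE)
cat("written: stats_t_tests.csv, stats_anova.csv, stats_te_anova.csv\n")
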