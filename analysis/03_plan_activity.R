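#!/usr/bin/env Rscript
# Activity planning on the planning-scan (MAA) measurements: partition-model
# plans under the default constraints (tumor > 120 Gy, lung < 20 Gy,
# in-target < 70 Gy or out-target < 30 Gy), and the BSA method with
# lung-shunt-based reduction for comparison.

suppressPackageStartupMessages(library(sirtdose))

meas <- read.csv("results/cohort_measurements.csv")
maa <- meas[meas$modality == "maa", ]
cons <- planning_constraints()

set.seed(20261)  # synthetic heights/weights for the BSA arm
plans <- do.call(rbind, lapply(split(maa, maa$case), function(sub) {
  voi <- function(k) {
    r <- sub[sub$compartment == k, ]
    voi_measurement(r$volume_ml, total_counts = r$total_counts)
  }
  m <- partition_measurements(voi("tumor"), voi("in_target"),
                              voi("out_target"),
                              lung_total_counts = sub$lung_total_counts[1],
                              lsf = sub$lsf[1])
  pm <- tryCatch(plan_partition_model(m, cons), error = function(e) NULL)
  height <- rnorm(1, 168, 8); weight <- rnorm(1, 68, 10)
  liver_ml <- sum(sub$volume_ml)
  bsa <- bsa_activity(height, weight, m$tumor$volume_ml, liver_ml)
  bsa_red <- tryCatch(lsf_reduction(bsa, m$lsf), error = function(e) NA_real_)
  data.frame(case = sub$case[1], lsf = m$lsf,
             excluded = is.null(pm),
             required_gbq = if (is.null(pm)) NA else pm$required_activity,
             recommended_gbq = if (is.null(pm)) NA else pm$recommended_activity,
             limiting = if (is.null(pm)) NA else pm$limiting_constraint,
             liver_limit_used = if (is.null(pm)) NA else pm$liver_limit_used,
             lung_tolerance_gbq = if (is.null(pm)) NA else pm$tolerance_activities[["lung"]],
             bsa_gbq = bsa, bsa_reduced_gbq = bsa_red)
}))
rownames(plans) <- NULL
write.csv(plans, "results/activity_plans.csv", row.names = FALSE)

ok <- !plans$excluded
cat(sprintf("PM required activity: %.1f +/- %.1f GBq (range %.1f-%.1f)\n",
            mean(plans$required_gbq[ok]), sd(plans$required_gbq[ok]),
            min(plans$required_gbq[ok]), max(plans$required_gbq[ok])))
cat(sprintf("BSA activity: %.1f +/- %.1f GBq\n",
            mean(plans$bsa_gbq), sd(plans$bsa_gbq)))
cat(sprintf("Capped plans: %d; excluded (LSF > %.1f): %d\n",
            sum(!is.na(plans$limiting) & ok), cons$lsf_exclusion,
            sum(plans$excluded)))
cat("Wrote results/activity_plans.csv\n")
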