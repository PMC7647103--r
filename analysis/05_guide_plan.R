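#!/usr/bin/env Rscript
# Step 5: the standardized ("universal") anterior reconstruction guide.
#
# Converts the cohort-mean anterior geometry into a fibular osteotomy plan
# and validates it against the perfusion constraint (no segment below
# 15 mm), then emits the default standardized plan: symphysis angle 120
# degrees, symphysis length 25 mm.
# Output: results/guide_plan.csv

library(mandimorph)

# plan derived from the measured cohort means
summ <- read.csv("results/summary_table.csv")
for (grp in unique(summ$group)) {
  spec <- guide_spec_from_summary(summ, grp)
  plan <- plan_anterior_guide(spec)
  message(sprintf("%s cohort mean geometry -> interior angle %.1f deg, wedges %.1f deg",
                  grp, plan$interior_angles[1], plan$wedge_angles[1]))
}

# the standardized default
plan <- plan_anterior_guide(guide_spec(symphysis_angle = 120,
                                       symphysis_length = 25,
                                       min_segment = 15))
v <- validate_plan(plan)
message("Standardized universal plan:")
print(plan)
message("Validation: ", if (v$pass) "pass" else paste(v$reasons, collapse = "; "))

out <- data.frame(segment = names(plan$segments),
                  length_mm = as.numeric(plan$segments))
out$wedge_after_deg <- c(plan$wedge_angles[1], plan$wedge_angles[2], NA)
write.csv(out, "results/guide_plan.csv", row.names = FALSE)
message("Wrote results/guide_plan.csv")
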