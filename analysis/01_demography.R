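#!/usr/bin/env Rscript
# Demographic reconstruction from stage-structured rearing counts.
#
# A seeded synthetic rearing experiment stands in for the laboratory data:
# five constant temperatures (17, 20, 26, 29, 35 degC), nine destructive
# colony openings every four days, ten tubes per opening. Egg hatching comes
# from a surrogate-species hatching table fitted with a quadratic. The
# output is the per-temperature life table: accumulated stage counts, stage
# survivals, net reproductive rate R0, generation time G, and intrinsic
# growth rate r = ln(R0)/G.

suppressPackageStartupMessages(library(ambrosiarisk))

seed <- 20240501L
dir.create("results", showWarnings = FALSE)

scenario <- synthetic_scenario(seed = seed)
cohort <- synth_cohort(scenario)
hatch_tab <- synth_hatching_table(scenario)

hatch_fit <- fit_hatching_polynomial(hatch_tab)
cat(sprintf("hatching quadratic: p(T) = %.5f T^2 + %.4f T + %.4f\n",
            hatch_fit$a, hatch_fit$b, hatch_fit$c))

summary <- suppressWarnings(demographic_summary(cohort, hatch_fit))
write.csv(summary, "results/demography_summary.csv", row.names = FALSE)

cat("\nPer-temperature demography:\n")
print(summary[, c("temperature", "p", "H", "R0", "G", "r", "viable")],
      digits = 4, row.names = FALSE)

viable <- summary[summary$viable, ]
cat(sprintf("\n%d of %d temperatures are viable (R0 > 0 with progeny females).\n",
            nrow(viable), nrow(summary)))
cat(sprintf("Growth peaks at %g degC (r = %.4f /day); the identity exp(r*G) = R0 holds to %.1e.\n",
            viable$temperature[which.max(viable$r)], max(viable$r),
            max(abs(exp(viable$r * viable$G) - viable$R0) / viable$R0)))
cat("wrote results/demography_summary.csv\n")
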