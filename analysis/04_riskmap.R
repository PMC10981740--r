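#!/usr/bin/env Rscript
# The r_i map: growth rate projected onto the landscape.
#
# The fitted growth curve from 02_growth_fit.R is evaluated on the mean
# annual temperature raster and multiplied by the binary suitability raster,
# giving the spatially varying growth coefficient of the metapopulation
# model. Unsuitable cells get r_i = 0 but stay in the grid (they can still
# pass migrants), exactly the role of the suitability mask upstream of the
# simulations.

suppressPackageStartupMessages(library(ambrosiarisk))

seed <- 20240501L
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/growth_model.json"))
  stop("run analysis/02_growth_fit.R first")

model <- read_growth_model("results/growth_model.json")
land <- synth_landscape(synthetic_scenario(seed = seed), corridors = TRUE)

rmap <- build_r_map(model, land$temperature, land$suitability)
write_asc(rmap, "results/ri_map.asc")

v <- rmap$values
cat(sprintf("r_i map: %d x %d cells at %.4f deg (~%.1f km)\n",
            nrow(v), ncol(v), rmap$cellsize, rmap$cellsize * 110.57))
cat(sprintf("  suitable cells: %d (%.1f%%), r_i range %.4f-%.4f /day\n",
            sum(v > 0), 100 * mean(v > 0), min(v[v > 0]), max(v)))
cat(sprintf("  implied carrying capacity at a = 1e-7: up to %s individuals/cell\n",
            format(max(v) / 1e-7, big.mark = ",")))
cat("wrote results/ri_map.asc\n")
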