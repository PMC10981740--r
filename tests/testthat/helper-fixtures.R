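# shared fixtures, all built in code

# point estimates of the published thermal growth curve (r_max, v_0, T_opt)
table1_model <- function() growth_model(0.1314, 0.0521, 26.2624)
table1_se <- c(r_max = 0.0113, v_0 = 0.0160, t_opt = 0.4137)

# minimal cohort: one temperature, explicit counts
make_cohort <- function(temperature = 26,
                        days = c(4, 8),
                        reps = 1L,
                        egg = 10, larva = 8, pupa = 6,
                        female_live = 4, female_dead = 1, male = 2) {
  grid <- expand.grid(day = days, replicate = seq_len(reps))
  data.frame(
    temperature = temperature, day = grid$day, replicate = grid$replicate,
    egg = egg, larva = larva, pupa = pupa,
    female_live = female_live, female_dead = female_dead, male = male)
}

# uniform-value raster helper
flat_raster <- function(value, nr = 5, nc = 5, cellsize = 2.5 / 60,
                        xll = -100, yll = 17) {
  grid_raster(matrix(value, nr, nc), xll, yll, cellsize)
}

# planar kernel with unit-friendly spacing: cells exactly `km` apart
planar_grid <- function(r_value, nr, nc, km = 4) {
  grid_raster(matrix(r_value, nr, nc), -100, 17, km / 111.32)
}
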