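# One-time calibration of the spectral-hardening parameter.
#
# The source model replaces the proprietary accelerator head with a
# thin-target spectrum hardened by an equivalent water filtration thickness.
# That thickness is the model's single spectral knob; it is fixed once by
# matching the tuned-beam 3.3 x 3.3 cm2 depth dose at 10 cm (SSD 78 cm,
# 0.35 T) to the commissioning value of 55.59%, and the result is stored as
# `SPECTRAL_HARDENING_MM` in R/source_model.R.
#
# Run from the package root:  Rscript tools/calibrate_hardening.R
# (several minutes; prints a PDD10-vs-thickness table and the selected value)

suppressMessages(library(mrdose))

target <- 55.59
candidates <- seq(50, 150, 20)
n_hist <- 8e6
seeds <- c(11, 12)

ph <- build_slab_phantom(list(slab("water", 300)), lateral_mm = 120,
                         spacing = c(3, 3, 2))
beam <- configure_beam(c(33, 33), ssd = 780)

pdd10 <- function(h, seed) {
  dg <- run_simulation(ph, beam,
                       config = transport_config(n_histories = n_hist,
                                                 seed = seed),
                       hardening_mm = h)
  p <- extract_pdd(dg, lateral_radius_vox = 2)
  stats::approx(p$positions, p$values, xout = 100)$y
}

tab <- data.frame(hardening_mm = candidates)
tab$pdd10 <- vapply(candidates, function(h)
  mean(vapply(seeds, function(s) pdd10(h, s), 0)), 0)
print(tab, row.names = FALSE)

# PDD10 saturates with thickness; select the smallest thickness within half
# a percentage point of the saturated best match
best <- tab$hardening_mm[which.min(abs(tab$pdd10 - target))]
cat(sprintf("selected hardening: %g mm (PDD10 target %.2f%%)\n",
            best, target))
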