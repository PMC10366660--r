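# Shared fixtures, generated in code and memoized for the session so that
# expensive simulations run once across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# rescale a population's concentration (in practice stocks are diluted so a
# manageable number of trajectories is recorded per second)
dilute <- function(spec, f) {
  population_spec(spec$name, spec$size_median, spec$size_iqr,
                  spec$ri_median, spec$ri_iqr, spec$concentration * f)
}

# diluted EV / VLDL stocks: ~700-800 kept trajectories in 20 s
stock_instrument <- function(duration_s = 20) instrument_spec(duration_s = duration_s)
stock_ev <- function() dilute(population_presets("EV")$EV, 1 / 6)
stock_vldl <- function() dilute(population_presets("VLDL")$VLDL, 1 / 40)

ev_stock_records <- function() {
  fixture("ev_stock_records", {
    s <- simulate_sample(stock_ev(), stock_instrument(), seed = 101)
    estimate_particles(s, compute_iqr = FALSE)
  })
}

vldl_stock_records <- function() {
  fixture("vldl_stock_records", {
    s <- simulate_sample(stock_vldl(), stock_instrument(), seed = 102)
    estimate_particles(s, compute_iqr = FALSE)
  })
}

ev_vldl_classifier <- function() {
  fixture("ev_vldl_classifier", {
    train_ev_classifier(ev_stock_records(), vldl_stock_records(), seed = 5)
  })
}

# monodisperse population helper (degenerate IQRs)
monodisperse <- function(diameter_nm, ri, concentration, name = "mono") {
  population_spec(name, diameter_nm, c(diameter_nm, diameter_nm),
                  ri, c(ri, ri), concentration)
}

# a hand-built single-leaf "forest" that predicts a constant probability;
# used to test the labelling rule at exact probability boundaries
constant_prob_classifier <- function(p, threshold = 0.8) {
  leaf <- list(var = 0L, thr = 0, left = 0L, right = 0L, prob = p,
               gain = numeric(3))
  structure(
    list(fit = list(trees = list(leaf), oob_accuracy = NA_real_,
                    importance = numeric(3), mtry = 1L, n_trees = 1L,
                    min_node = 1L),
         confidence_threshold = threshold,
         features = c("diameter_nm", "log10_sigma", "ri"),
         n_train = c(EV = 0L, LP = 0L), seed = NA_integer_),
    class = "inta_classifier")
}
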