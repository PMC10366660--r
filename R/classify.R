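#' Train the EV vs lipoprotein random-forest classifier
#'
#' Fits a random forest (balanced-bootstrap bagged CART, Gini splits, grown
#' to purity) on per-particle features (diameter, log10 cross-section,
#' refractive index) from labelled pure-sample records. For each particle
#' the forest returns the probability of it being an EV; particles are
#' labelled only when that probability clears a confidence threshold, so
#' ambiguous particles in the size-RI overlap region stay unclassified
#' rather than polluting either count.
#'
#' @param ev_records,lp_records Particle record tibbles ([estimate_particles()]
#'   output) measured on pure EV and pure LP samples; at least 100 records
#'   each.
#' @param n_trees Number of trees (default 200).
#' @param mtry Features tried per split; default `floor(sqrt(3)) = 1`.
#' @param min_node Minimum records per node before a split is attempted.
#' @param confidence_threshold Probability needed to assign a label, in
#'   (0.5, 1); default 0.8. `p_ev >= threshold` labels EV (ties to EV),
#'   `p_ev <= 1 - threshold` labels LP, anything between is unclassified.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An `inta_classifier` object; see [tidy()]/[glance()] methods and
#'   [classify_particles()].
#' @export
train_ev_classifier <- function(ev_records, lp_records, n_trees = 200,
                                mtry = NULL, min_node = 1L,
                                confidence_threshold = 0.8, seed = 1L) {
  if (confidence_threshold <= 0.5 || confidence_threshold >= 1) {
    abort("`confidence_threshold` must be in (0.5, 1).")
  }
  if (nrow(ev_records) < 100 || nrow(lp_records) < 100) {
    abort(sprintf(
      "Need >= 100 records per class for training (got %d EV, %d LP).",
      nrow(ev_records), nrow(lp_records)))
  }
  X <- rbind(classifier_features(ev_records, "ev_records"),
             classifier_features(lp_records, "lp_records"))
  y <- rep(c(1, 0), c(nrow(ev_records), nrow(lp_records)))
  fit <- rf_fit(X, y, n_trees = n_trees, mtry = mtry, min_node = min_node,
                seed = seed)
  structure(
    list(fit = fit, confidence_threshold = confidence_threshold,
         features = colnames(X),
         n_train = c(EV = nrow(ev_records), LP = nrow(lp_records)),
         seed = seed),
    class = "inta_classifier")
}

classifier_features <- function(records, what) {
  required_cols(records, c("diameter_nm", "sigma_nm2", "ri"), what)
  bad <- !stats::complete.cases(records[, c("diameter_nm", "sigma_nm2", "ri")])
  if (any(bad)) {
    ids <- if ("particle_id" %in% names(records)) {
      paste(head(records$particle_id[bad], 5), collapse = ", ")
    } else {
      paste(head(which(bad), 5), collapse = ", ")
    }
    abort(sprintf("%s has missing feature values (e.g. particle(s) %s).",
                  what, ids))
  }
  cbind(diameter_nm = records$diameter_nm,
        log10_sigma = log10(records$sigma_nm2 + 1e-6),
        ri = records$ri)
}

#' @export
print.inta_classifier <- function(x, ...) {
  cat(sprintf(
    paste0("<inta_classifier> %d trees, mtry %d, threshold %.2f, ",
           "OOB accuracy %.3f (trained on %d EV / %d LP)\n"),
    x$fit$n_trees, x$fit$mtry, x$confidence_threshold, x$fit$oob_accuracy,
    x$n_train["EV"], x$n_train["LP"]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.inta_classifier <- function(x, ...) {
  tibble(feature = x$features,
         importance = as.numeric(x$fit$importance))
}

#' @exportS3Method generics::glance
glance.inta_classifier <- function(x, ...) {
  tibble(n_trees = x$fit$n_trees, mtry = x$fit$mtry,
         min_node = x$fit$min_node,
         confidence_threshold = x$confidence_threshold,
         oob_accuracy = x$fit$oob_accuracy,
         n_train_ev = unname(x$n_train["EV"]),
         n_train_lp = unname(x$n_train["LP"]))
}

#' Classify particle records as EV, LP or unclassified
#'
#' Applies a trained classifier to particle records. Each record gets the
#' forest probability `p_ev` and a three-way label: `"EV"` when
#' `p_ev >= threshold` (boundary ties to EV), `"LP"` when
#' `p_ev <= 1 - threshold`, otherwise `"unclassified"`.
#'
#' @param records Particle record tibble with `diameter_nm`, `sigma_nm2`,
#'   `ri` columns.
#' @param model An `inta_classifier` from [train_ev_classifier()].
#' @return `records` with `p_ev` and `label` columns appended; carries class
#'   `inta_classified`.
#' @export
classify_particles <- function(records, model) {
  stopifnot(inherits(model, "inta_classifier"))
  X <- classifier_features(records, "`records`")
  p <- rf_predict(model$fit, X)
  thr <- model$confidence_threshold
  # small numerical guard so that p exactly at a boundary counts as
  # confident (ties go to the label, EV side at p == threshold)
  eps <- 1e-9
  out <- dplyr::mutate(
    records, p_ev = p,
    label = dplyr::case_when(p >= thr - eps ~ "EV",
                             p <= 1 - thr + eps ~ "LP",
                             TRUE ~ "unclassified"))
  class(out) <- c("inta_classified", class(out))
  out
}

#' Relative EV concentration
#'
#' The count-based ratio `n_EV / (n_EV + n_LP)` among confidently classified
#' records; unclassified records are excluded from both numerator and
#' denominator. Because every classified trajectory maps to concentration
#' through the same calibration factor, the count ratio equals the
#' concentration ratio `C_EV / (C_EV + C_LP)`.
#'
#' @param classified Output of [classify_particles()].
#' @return A single fraction in `[0, 1]`.
#' @export
relative_ev_concentration <- function(classified) {
  required_cols(classified, "label", "`classified`")
  n_ev <- sum(classified$label == "EV")
  n_lp <- sum(classified$label == "LP")
  if (n_ev + n_lp == 0) {
    abort("No confidently classified records: relative EV concentration undefined.")
  }
  n_ev / (n_ev + n_lp)
}

#' Misclassification report for ground-truth-labelled samples
#'
#' For records carrying a ground-truth population label (simulated samples,
#' or measured pure samples), tabulates per-class error rates among the
#' confidently classified records plus the unclassified fraction. EVs
#' labelled LP and LPs labelled EV are the two error modes a sample-purity
#' analysis needs.
#'
#' @param classified Output of [classify_particles()] with a truth column.
#' @param truth_col Column holding the true population label.
#' @param ev_populations Truth values counting as EV (default `"EV"`); all
#'   others count as LP.
#' @return A tibble with one row per true class: `true_class`, `n`,
#'   `n_classified`, `mislabel_rate` (errors among classified),
#'   `unclassified_fraction`.
#' @export
misclassification_report <- function(classified, truth_col = "population",
                                     ev_populations = "EV") {
  required_cols(classified, c("label", truth_col), "`classified`")
  truth <- ifelse(classified[[truth_col]] %in% ev_populations, "EV", "LP")
  dplyr::summarise(
    dplyr::group_by(tibble(truth = truth, label = classified$label),
                    true_class = truth),
    n = dplyr::n(),
    n_classified = sum(.data$label != "unclassified"),
    mislabel_rate = ifelse(.data$n_classified == 0, NA_real_,
                           sum(.data$label != "unclassified" &
                                 .data$label != .data$true_class) /
                             .data$n_classified),
    unclassified_fraction = mean(.data$label == "unclassified"),
    .groups = "drop")
}
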