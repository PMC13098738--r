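# Shared fixtures and independent oracles for the test suite.

# homogeneous one-layer model (semi-infinite unless thickness_mm given)
homog_model <- function(mua, musp, g = 0.8, n = 1.0, thickness_mm = 2e2,
                        wavelength = 800, ambient_n = 1.0) {
  lay <- layer_spec("medium", thickness_mm * 1000, g = g, n = n,
                    mua = setNames(mua, wavelength),
                    musp = setNames(musp, wavelength))
  tissue_model(list(lay), wavelengths = wavelength, ambient_n = ambient_n)
}

# hand-constructed tally with explicit records (for single-photon cases)
manual_tally <- function(exit_weight, exit_radius, zmax, n_launched,
                         path_lengths = NULL,
                         layer_names = "medium", boundaries_mm = c(0, 10),
                         wavelength = 800) {
  k <- length(exit_weight)
  if (is.null(path_lengths))
    path_lengths <- matrix(0, k, length(layer_names))
  colnames(path_lengths) <- layer_names
  structure(list(
    exit_weight = exit_weight, exit_radius = exit_radius, zmax = zmax,
    path_lengths = path_lengths,
    collisions = matrix(0L, k, length(layer_names),
                        dimnames = list(NULL, layer_names)),
    n_launched = n_launched,
    total_absorbed_weight = n_launched - sum(exit_weight),
    total_transmitted_weight = 0, specular_weight = 0,
    model_label = "baseline", melanin_level = 0,
    wavelength = wavelength, seed = 0L,
    layer_names = layer_names, boundaries_mm = boundaries_mm
  ), class = "photon_tally")
}

# brute-force all-pairs AUC oracle (lower value indicates patient)
auc_bruteforce <- function(patient, control) {
  s <- 0
  for (p in patient) for (c0 in control)
    s <- s + (p < c0) + 0.5 * (p == c0)
  s / (length(patient) * length(control))
}

# trapezoidal area under a stored ROC curve
roc_trapezoid <- function(roc) {
  fpr <- 1 - roc$specificities
  o <- order(fpr, roc$sensitivities)
  sum(diff(fpr[o]) * (head(roc$sensitivities[o], -1) +
                        tail(roc$sensitivities[o], -1)) / 2)
}

# enumerated placement values for the DeLong variance oracle
# (higher score = more patient-like)
placement_oracle <- function(scores_patient, scores_control) {
  v10 <- sapply(scores_patient, function(x)
    mean((x > scores_control) + 0.5 * (x == scores_control)))
  v01 <- sapply(scores_control, function(y)
    mean((scores_patient > y) + 0.5 * (scores_patient == y)))
  m <- length(scores_patient); n <- length(scores_control)
  list(auc = mean(v10),
       var = stats::var(v10) / m + stats::var(v01) / n)
}
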