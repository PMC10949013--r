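# In-code fixtures: random regression instances and small oxide sets.

random_linear_instance <- function(n, p, noise = 1, seed = 1,
                                   beta = NULL, intercept = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- rnorm(p)
  y <- intercept + drop(X %*% beta) + rnorm(n, 0, noise)
  tab <- as.data.frame(X)
  tab$y <- y
  list(table = tab, features = colnames(X), beta = beta, intercept = intercept)
}

# formulas named in the study text, with a few pool extras
study_formulas <- function() {
  c("WO3", "NiO", "Mn2O3", "Co3O4", "Yb2O3", "SnO2", "CoO", "TiO2", "CuO",
    "Sb2O3", "Fe3O4", "Al2O3", "Cr2O3", "ZnO", "Y2O3", "Fe2O3", "MnO2",
    "ZrO2")
}

# independent normal-equations oracle (pseudo-inverse path, no qr)
ols_oracle <- function(X, y) {
  Xi <- cbind(1, X)
  drop(solve(t(Xi) %*% Xi) %*% t(Xi) %*% y)
}
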