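# Independent oracles and small fixture builders shared across tests.

# step-by-step MCWD recursion, written independently of the package internals
mcwd_oracle <- function(p, e) {
  cwd <- 0
  worst <- 0
  for (m in seq_along(p)) {
    cwd <- cwd + p[m] - e[m]
    if (cwd > 0) cwd <- 0
    if (cwd < worst) worst <- cwd
  }
  abs(worst)
}

# real roots of -x^3 + x + c, sorted; the stable ones are the outer roots
cubic_roots_oracle <- function(c_eff) {
  r <- polyroot(c(c_eff, 1, 0, -1)) # c + x - x^3
  sort(Re(r[abs(Im(r)) < 1e-8]))
}

# long-format monthly field from a per-cell x month matrix
field_from_matrix <- function(m, years, months = NULL, cell_ids = seq_len(nrow(m)) - 1L) {
  nm <- ncol(m)
  if (is.null(months)) {
    months <- rep(1:12, length.out = nm)
    yrs <- rep(years, each = 12)[seq_len(nm)]
  } else {
    yrs <- years
  }
  tibble::tibble(
    cell_id = rep(cell_ids, times = nm),
    year = rep(yrs, each = nrow(m)),
    month = rep(months, each = nrow(m)),
    value = as.vector(m)
  )
}

# single-cell monthly fields over whole calendar years
one_cell_field <- function(values, start_year = 2000) {
  stopifnot(length(values) %% 12 == 0)
  ny <- length(values) / 12
  tibble::tibble(
    cell_id = 0L,
    year = rep(start_year + seq_len(ny) - 1L, each = 12),
    month = rep(1:12, times = ny),
    value = values
  )
}

# hand-workable forcing/profile/coupling fixtures for the dynamics tests
toy_forcing <- function(c_crit, c_map = c_crit, c_mcwd = 0) {
  tibble::tibble(
    cell_id = seq_along(c_crit) - 1L,
    c_map = rep_len(c_map, length(c_crit)),
    c_mcwd = rep_len(c_mcwd, length(c_crit)),
    c_crit = c_crit,
    tippable = TRUE
  )
}

toy_coupling <- function(source, target, r) {
  structure(tibble::tibble(source = source, target = target, r = r),
            class = c("coupling_matrix", "tbl_df", "tbl", "data.frame"))
}

# The binary cascade can only mirror the smooth dynamics when margins hold
# against the *graded* equilibrium too: stressed-but-stable sources sit above
# x = -1 and leak partial coupling w((x+1)/2) > 0. This solves the graded
# fixed point semi-analytically (tipped sources at weight 1, untipped at the
# weight of their stable forest root) and reports each untipped cell's
# effective forcing, or NULL if an untipped cell is pushed within `margin`
# of (or past) the critical value.
graded_margin_ok <- function(cc, cm, tipped, margin) {
  cs <- c_star()
  n <- length(cc)
  untipped <- setdiff(seq_len(n) - 1L, tipped)
  w <- rep(1, n)
  w[untipped + 1L] <- 0
  for (iter in 1:200) {
    eff <- cc
    for (k in seq_len(nrow(cm))) {
      eff[cm$target[k] + 1L] <- eff[cm$target[k] + 1L] + cm$r[k] * w[cm$source[k] + 1L]
    }
    if (any(eff[untipped + 1L] > cs - margin)) return(FALSE)
    w_new <- w
    for (i in untipped) {
      x_neg <- min(cubic_roots_oracle(eff[i + 1L]))
      w_new[i + 1L] <- (x_neg + 1) / 2
    }
    if (max(abs(w_new - w)) < 1e-10) return(TRUE)
    w <- w_new
  }
  FALSE
}

# random sparse network instances for oracle-equivalence checks; rejected and
# redrawn until every cell's effective forcing stays clear of the critical
# value at every pass of the binary cascade and at the graded equilibrium
random_cascade_instance <- function(seed, margin = 0.02) {
  set.seed(seed)
  repeat {
    n <- sample(8:12, 1)
    cc <- runif(n, 0, 0.45)
    pairs <- expand.grid(source = 0:(n - 1), target = 0:(n - 1))
    pairs <- pairs[pairs$source != pairs$target, ]
    keep <- runif(nrow(pairs)) < 0.25
    cm <- toy_coupling(pairs$source[keep], pairs$target[keep],
                       runif(sum(keep), 0.02, 0.12))
    f <- toy_forcing(cc)
    tip <- discrete_cascade(f, cm)
    if (attr(tip, "margin") >= margin &&
        graded_margin_ok(cc, cm, as.integer(tip), margin)) {
      return(list(forcing = f, coupling = cm, tipped = as.integer(tip)))
    }
  }
}

# quick scenario ensemble used by several tests (kept deliberately small)
tiny_scenario <- function(name = "strong_drying", nx = 8, ny = 8, seed = 5,
                          n_members = 2, ...) {
  cfg <- model_config(dt = 0.2, t_max = 1200, n_members = n_members)
  run_scenario(scenario_preset(name, seed = seed), nx = nx, ny = ny,
               config = cfg, master_seed = seed, ...)
}
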