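# Independent oracles and fixture builders shared across the suite.

# Exhaustive per-Red minima by explicit double loops (no vectorization).
brute_force_minima <- function(red, green, farred) {
  out <- data.frame(rg_min = numeric(nrow(red)), rfr_min = numeric(nrow(red)))
  for (i in seq_len(nrow(red))) {
    best_g <- Inf
    for (j in seq_len(nrow(green))) {
      d <- sqrt((red$x[i] - green$x[j])^2 + (red$y[i] - green$y[j])^2)
      if (d < best_g) best_g <- d
    }
    best_f <- Inf
    for (j in seq_len(nrow(farred))) {
      d <- sqrt((red$x[i] - farred$x[j])^2 + (red$y[i] - farred$y[j])^2)
      if (d < best_f) best_f <- d
    }
    out$rg_min[i] <- best_g
    out$rfr_min[i] <- best_f
  }
  out
}

# Brute-force event class from the definitions, written independently of the
# package's vectorized classifier.
brute_force_class <- function(rg_min, rfr_min, t) {
  cls <- character(length(rg_min))
  for (i in seq_along(rg_min)) {
    if (rg_min[i] > t && rfr_min[i] <= t) {
      cls[i] <- "translocation"
    } else if (rg_min[i] > t) {
      cls[i] <- "breakage"
    } else {
      cls[i] <- "intact"
    }
  }
  cls
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (probability-mass convention).
fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  ks <- max(0, n1 - m2):min(n1, m1)
  pr <- stats::dhyper(ks, m1, m2, n1)
  pobs <- stats::dhyper(a, m1, m2, n1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Random spot table for one synthetic nucleus (coordinates only).
random_nucleus_spots <- function(n_red, n_green, n_farred, span = 30) {
  list(red = data.frame(x = runif(n_red, 0, span),
                        y = runif(n_red, 0, span)),
       green = data.frame(x = runif(n_green, 0, span),
                          y = runif(n_green, 0, span)),
       farred = data.frame(x = runif(n_farred, 0, span),
                           y = runif(n_farred, 0, span)))
}

# Convert a sim_field ground truth into the mid-way (nuclei, spots) table
# dialect, with one nucleus per simulated cell.
truth_tables <- function(sim) {
  sp <- sim$truth$spots
  sp$nucleus_id <- sp$cell_id
  nuc <- unique(sp[, c("field_id", "nucleus_id")])
  list(nuclei = nuc, spots = sp)
}

# Simulate ground truth only (no rendering) for n_cells, in fields of
# `per_field`, and return concatenated truth/event inputs.
simulate_truth_only <- function(cm, n_cells, seed0, per_field = 10,
                                imaging = imaging_config()) {
  n_fields <- ceiling(n_cells / per_field)
  nuc <- vector("list", n_fields); sp <- vector("list", n_fields)
  al <- vector("list", n_fields)
  left <- n_cells
  for (f in seq_len(n_fields)) {
    fid <- sprintf("f%04d", f)
    sim <- simulate_field(cm, min(per_field, left), imaging = imaging,
                          seed = seed0 + f, field_id = fid, render = FALSE)
    left <- left - per_field
    tt <- truth_tables(sim)
    nuc[[f]] <- tt$nuclei; sp[[f]] <- tt$spots
    al[[f]] <- sim$truth$alleles
  }
  list(nuclei = do.call(rbind, nuc), spots = do.call(rbind, sp),
       alleles = do.call(rbind, al))
}

# Small imaging geometry used in image-based unit tests.
test_imaging <- function(shape = c(128L, 128L)) {
  imaging_config(field_shape_px = shape)
}

# Irradiated-type cell model with the stated cell-level event frequencies
# (breakage 2% of cells, translocation 0.4% of cells, three gene-A alleles).
irradiated_model <- function() {
  p_break_allele <- 1 - (1 - 0.02)^(1 / 3)
  p_tr_allele <- 1 - (1 - 0.004)^(1 / 3)
  cell_model("M2A-IR", p_break = p_break_allele,
             p_transloc_given_break = p_tr_allele / p_break_allele)
}

# Translocation-positive line: four alleles of both genes, every broken
# allele joined to a partner.
positive_model <- function() {
  cell_model("K299", n_alleles_A = 4, n_alleles_B = 4,
             p_break = 0.5, p_transloc_given_break = 1)
}
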