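# Fixtures built in code. The "WT-like" linker below is a SYNTHETIC
# stand-in with the descriptor counts of a reference bacterial LPMO linker
# (34 residues; 8 Pro, 2 Asp, 2 Glu, 1 Lys), not a database sequence.
SYN_WT_LINKER <- "TPGPSTDGTPKTPENGTSGTPDSTPGNGEPTSGP"

# Parent with the reference domain architecture: leading segment 1-34,
# AA10 domain 35-228, linker 229-262, CBM2 domain 263-364.
make_synthetic_parent <- function(linker = SYN_WT_LINKER) {
  filler <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "G", "V", "L", "S", "T", "N", "Y", "W", "F"), n,
                 replace = TRUE), collapse = "")
  }
  paste0(filler(34, 101), filler(194, 102), linker, filler(102, 103))
}

synthetic_domain_annotations <- function(parent_id = "synthetic_lpmo10c") {
  data.frame(parent_id = parent_id,
             domain_name = c("AA10", "CBM2"),
             start_res = c(35L, 263L), end_res = c(228L, 364L),
             stringsAsFactors = FALSE)
}

# Small deterministic ensemble from explicit coordinates.
toy_ensemble <- function(frames, sequence) {
  nf <- length(frames)
  n <- nrow(frames[[1]])
  co <- array(0, c(nf, n, 3))
  for (f in seq_len(nf)) co[f, , ] <- frames[[f]]
  ensemble(co, sequence)
}

# Straight rod along x with given bond length.
rod_coords <- function(n, lb = 0.38) cbind((seq_len(n) - 1) * lb, 0, 0)

# Freely-jointed chain frames (unit-independent ideal chain).
fjc_coords <- function(n, lb = 0.38) {
  z <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  steps <- lb * z / sqrt(rowSums(z^2))
  rbind(0, apply(steps, 2, cumsum))
}

poly <- function(letter, n) paste(rep(letter, n), collapse = "")

# Short production config for module-level simulation tests.
quick_config <- function(total_time = 10, seed = 1L, ...) {
  suppressWarnings(model_config(total_time = total_time, timestep = 0.01,
                                frame_stride = 20, seed = seed, ...))
}

# Exact sphere form-factor profile of radius R (nm), I(0) = 1, with
# constant absolute uncertainty (counting-statistics-like weighting).
sphere_profile <- function(R, qmax = 2.0, n = 120) {
  q <- seq(qmax / n, qmax, length.out = n)
  x <- q * R
  ff <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  scattering_profile(q, ff, sigma = rep(1e-3, n))
}
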