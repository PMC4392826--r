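#' Elastic network model parameters
#'
#' Parameter bundle for the Gaussian network model. Residues whose C-alpha
#' atoms lie within `cutoff` of each other are joined by identical springs of
#' stiffness `gamma`; `kT` sets the thermal energy scale of all fluctuation
#' quantities. Both `gamma` and `kT` are global scale factors (the model's
#' outputs are in arbitrary units unless calibrated), so their defaults are 1.
#'
#' @param cutoff contact cutoff in Angstrom. The first coordination shell of
#'   a residue spans roughly 6.5-7.0 A; default 7.0.
#' @param gamma spring constant (energy / Angstrom^2), > 0.
#' @param kT thermal energy in the same units as `gamma * Angstrom^2`.
#' @param mode_selection which eigenmodes enter fluctuation sums: one of
#'   `"all-nonzero"`, `"fastest:k"` (the k largest eigenvalues, localized
#'   high-frequency modes that resolve residue-level hotspots) or
#'   `"slowest:k"` (the k smallest nonzero eigenvalues, global motions).
#'   Default `"fastest:5"`: five fast modes suffice to represent
#'   residue-level fluctuations.
#'
#' @return List of class `enm_params`.
#' @export
enm_params <- function(cutoff = 7.0, gamma = 1, kT = 1,
                       mode_selection = "fastest:5") {
  stopifnot(cutoff > 0, gamma > 0, kT > 0)
  parse_mode_selection(mode_selection)  # validate syntax
  structure(list(cutoff = cutoff, gamma = gamma, kT = kT,
                 mode_selection = mode_selection),
            class = "enm_params")
}

# "all-nonzero" | "fastest:k" | "slowest:k"  ->  list(type, k)
parse_mode_selection <- function(selection) {
  if (inherits(selection, "mode_selection")) return(selection)
  stopifnot(is.character(selection), length(selection) == 1L)
  if (selection %in% c("all-nonzero", "all"))
    return(structure(list(type = "all-nonzero", k = NA_integer_),
                     class = "mode_selection"))
  m <- regmatches(selection,
                  regexec("^(fastest|slowest|fast|slow):([0-9]+)$", selection))[[1L]]
  if (length(m) == 0L)
    stop("invalid mode selection '", selection,
         "'; use 'all-nonzero', 'fastest:k' or 'slowest:k'")
  k <- as.integer(m[3L])
  if (k < 1L) stop("mode selection k must be >= 1")
  type <- c(fast = "fastest", fastest = "fastest",
            slow = "slowest", slowest = "slowest")[[m[2L]]]
  structure(list(type = type, k = k), class = "mode_selection")
}

#' Build the Kirchhoff (connectivity) matrix of a C-alpha trace
#'
#' Forms the binary contact matrix `C` (`C_ij = 1` iff `i != j` and the
#' CA-CA distance is at most the cutoff) and the Kirchhoff matrix
#' `Gamma = gamma * (diag(rowSums(C)) - C)` — the graph Laplacian of the
#' contact graph scaled by the spring constant. `Gamma` is symmetric and
#' positive semidefinite with zero row sums; its null space dimension equals
#' the number of connected components of the contact graph.
#'
#' @param trace a [calpha_trace()] of length >= 2.
#' @param params an [enm_params()] bundle.
#'
#' @return List of class `kirchhoff` with elements `matrix` (Gamma),
#'   `contacts` (0/1 matrix `C`), `params`, and the trace's residue
#'   bookkeeping (`resnum`, `chain`, `icode`, `aa`, `labels`, `coords`,
#'   `b_exp`). Residues with no contact at all trigger a warning.
#' @export
#' @examples
#' tr <- generate_synthetic_trace(3, "linear", noise_sd = 0)
#' build_kirchhoff(tr, enm_params(cutoff = 7))$matrix
build_kirchhoff <- function(trace, params = enm_params()) {
  stopifnot(inherits(trace, "calpha_trace"))
  if (nrow(trace) < 2L) stop("trace must contain at least 2 residues")
  stopifnot(inherits(params, "enm_params"))
  xyz <- trace_coords(trace)
  d <- as.matrix(stats::dist(xyz))
  C <- (d <= params$cutoff) * 1
  diag(C) <- 0
  deg <- rowSums(C)
  if (any(deg == 0))
    warning(sum(deg == 0), " residue(s) with no contacts at cutoff ",
            params$cutoff, " A: ",
            paste(residue_labels(trace)[deg == 0], collapse = ", "))
  G <- params$gamma * (diag(deg) - C)
  structure(list(matrix = G, contacts = C, params = params,
                 resnum = trace$resnum, chain = trace$chain,
                 icode = trace$icode, aa = trace$one_letter,
                 labels = residue_labels(trace), coords = xyz,
                 b_exp = trace$b),
            class = "kirchhoff")
}

#' @export
print.kirchhoff <- function(x, ...) {
  n <- nrow(x$matrix)
  cat(sprintf(
    "Kirchhoff matrix: %d residues, cutoff %.2f A, gamma %g, %d contacts\n",
    n, x$params$cutoff, x$params$gamma, sum(x$contacts) / 2))
  invisible(x)
}

#' Eigendecompose a Kirchhoff matrix
#'
#' @param K a `kirchhoff` object from [build_kirchhoff()].
#' @param zero_tol relative tolerance: eigenvalues below
#'   `zero_tol * max(eigenvalue)` count as zero modes. One zero mode exists
#'   per connected component of the contact graph.
#'
#' @return List of class `mode_spectrum`: `values` (nondecreasing
#'   eigenvalues), `vectors` (orthonormal columns, matching order),
#'   `n_zero_modes`, and the parent's residue bookkeeping.
#' @export
eigendecompose <- function(K, zero_tol = 1e-8) {
  stopifnot(inherits(K, "kirchhoff"))
  e <- eigen(K$matrix, symmetric = TRUE)
  ord <- order(e$values)  # eigen() returns decreasing; ascending here
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  vmax <- max(values)
  n_zero <- if (vmax <= 0) length(values) else sum(values < zero_tol * vmax)
  structure(list(values = values, vectors = vectors, n_zero_modes = n_zero,
                 gamma = K$params$gamma, resnum = K$resnum,
                 labels = K$labels, aa = K$aa),
            class = "mode_spectrum")
}

# mode indices (into ascending order) for a parsed selection
select_modes <- function(spectrum, selection) {
  sel <- parse_mode_selection(selection)
  n <- length(spectrum$values)
  nz <- seq.int(spectrum$n_zero_modes + 1L, n)
  if (spectrum$n_zero_modes >= n) stop("spectrum has no nonzero modes")
  switch(sel$type,
    `all-nonzero` = nz,
    fastest = {
      if (sel$k > length(nz))
        stop("requested ", sel$k, " fastest modes but only ", length(nz),
             " nonzero modes available")
      utils::tail(nz, sel$k)
    },
    slowest = {
      if (sel$k > length(nz))
        stop("requested ", sel$k, " slowest modes but only ", length(nz),
             " nonzero modes available")
      utils::head(nz, sel$k)
    })
}

#' Mode-restricted inverse (fluctuation correlation matrix)
#'
#' Computes `kT * sum_m (1/lambda_m) u_m u_m^T` over the selected nonzero
#' modes: the residue fluctuation cross-correlations
#' `<dR_i . dR_j> = kT (Gamma^-1)_ij`, with the inverse taken as the
#' Moore-Penrose pseudo-inverse when all nonzero modes are selected, or
#' restricted to a mode subset (e.g. the five fastest) otherwise.
#'
#' @param spectrum a `mode_spectrum` from [eigendecompose()].
#' @param selection mode selection string (see [enm_params()]).
#' @param kT thermal energy scale.
#'
#' @return Matrix of class `enm_corr` with attributes `modes_used` (indices
#'   into the ascending spectrum) and `kT`.
#' @export
mode_restricted_inverse <- function(spectrum, selection = "all-nonzero",
                                    kT = 1) {
  stopifnot(inherits(spectrum, "mode_spectrum"), kT > 0)
  modes <- select_modes(spectrum, selection)
  U <- spectrum$vectors[, modes, drop = FALSE]
  lam <- spectrum$values[modes]
  M <- kT * (U %*% (t(U) / lam))
  M <- (M + t(M)) / 2  # enforce exact symmetry against roundoff
  structure(M, class = c("enm_corr", "matrix"), modes_used = modes, kT = kT,
            resnum = spectrum$resnum, labels = spectrum$labels,
            aa = spectrum$aa)
}

#' Predicted B-factors from mean-square fluctuations
#'
#' Converts per-residue mean-square fluctuations `<(dR_i)^2>` (the diagonal
#' of the correlation matrix, computed with all nonzero modes) to
#' crystallographic B-factors via `B_i = (8 pi^2 / 3) <(dR_i)^2>`. When
#' experimental B-factors are supplied, a single least-squares scalar maps
#' predicted onto experimental values (the model's `kT/gamma` scale is
#' arbitrary), and their Pearson correlation is reported.
#'
#' @param corr an `enm_corr` matrix (use `selection = "all-nonzero"`).
#' @param b_exp optional experimental B-factors (Angstrom^2), length n.
#'
#' @return Data frame with columns `resnum`, `aa`, `msf`, `b_pred` and,
#'   when `b_exp` is given, `b_scaled` (least-squares rescaled prediction)
#'   plus attributes `scale` and `pearson`.
#' @export
predicted_bfactors <- function(corr, b_exp = NULL) {
  stopifnot(inherits(corr, "enm_corr"))
  msf <- diag(unclass(corr))
  b_pred <- (8 * pi^2 / 3) * msf
  out <- data.frame(resnum = attr(corr, "resnum"), aa = attr(corr, "aa"),
                    msf = msf, b_pred = b_pred)
  if (!is.null(b_exp) && any(is.finite(b_exp))) {
    ok <- is.finite(b_exp)
    scale <- sum(b_exp[ok] * b_pred[ok]) / sum(b_pred[ok]^2)
    out$b_exp <- b_exp
    out$b_scaled <- b_pred * scale
    attr(out, "scale") <- scale
    attr(out, "pearson") <- stats::cor(b_pred[ok], b_exp[ok])
  }
  out
}

#' Mean-square fluctuation of an inter-residue distance
#'
#' `<(dR_ij)^2> = corr_ii - 2 corr_ij + corr_jj`: the variance of the
#' distance between residues i and j induced by the selected modes. Zero
#' when `i == j`, symmetric in its arguments.
#'
#' @param corr an `enm_corr` matrix.
#' @param i,j positional residue indices (1-based).
#' @return Scalar value (Angstrom^2 up to the kT/gamma scale).
#' @export
distance_fluctuation <- function(corr, i, j) {
  n <- nrow(corr)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop("residue index out of range 1..", n)
  unclass(corr)[i, i] - 2 * unclass(corr)[i, j] + unclass(corr)[j, j]
}

#' Per-residue energy-response profile
#'
#' The energy response of residue i is the sum of mean-square distance
#' fluctuations with all of its contact neighbours,
#' `dU_i = sum_{j : C_ij = 1} <(dR_ij)^2>`. Harmonic interaction energy
#' fluctuations are proportional to distance fluctuations, so `dU_i`
#' measures how strongly residue i exchanges fluctuational energy with its
#' surroundings; computed over the fastest modes it highlights localized,
#' energetically responsive (hotspot) residues. Units are arbitrary and
#' unnormalized.
#'
#' @param corr an `enm_corr` matrix (typically restricted to fast modes).
#' @param K the `kirchhoff` object sharing the same residue indexing.
#' @param corr_full optional second `enm_corr` computed with all nonzero
#'   modes, used for the `msf`/`b_pred` columns (B-factor comparison uses
#'   the full spectrum). Defaults to `corr` itself.
#'
#' @return Data frame of class `response_profile` with columns `chain`,
#'   `resnum`, `icode`, `aa`, `msf`, `b_pred`, `b_exp`, `energy_response`.
#' @export
#' @examples
#' tr <- generate_synthetic_trace(30, "helix", noise_sd = 0)
#' K <- build_kirchhoff(tr)
#' sp <- eigendecompose(K)
#' fast <- mode_restricted_inverse(sp, "fastest:5")
#' head(energy_response_profile(fast, K))
energy_response_profile <- function(corr, K, corr_full = NULL) {
  stopifnot(inherits(corr, "enm_corr"), inherits(K, "kirchhoff"))
  n <- nrow(K$matrix)
  if (nrow(corr) != n)
    stop("correlation matrix (", nrow(corr), ") and Kirchhoff matrix (", n,
         ") dimensions differ")
  if (!identical(attr(corr, "resnum"), K$resnum))
    stop("correlation matrix and Kirchhoff matrix index maps differ")
  M <- unclass(corr)
  C <- K$contacts
  dM <- diag(M)
  # dU_i = sum_j C_ij (M_ii - 2 M_ij + M_jj), vectorized
  du <- dM * rowSums(C) + as.vector(C %*% dM) - 2 * rowSums(C * M)
  du <- pmax(du, 0)  # guard tiny negative roundoff
  base <- if (is.null(corr_full)) corr else corr_full
  msf <- diag(unclass(base))
  out <- data.frame(chain = K$chain, resnum = K$resnum, icode = K$icode,
                    aa = K$aa, msf = msf, b_pred = (8 * pi^2 / 3) * msf,
                    b_exp = K$b_exp, energy_response = du,
                    stringsAsFactors = FALSE)
  attr(out, "modes_used") <- attr(corr, "modes_used")
  class(out) <- c("response_profile", "data.frame")
  out
}

#' One-call ENM profile of a trace
#'
#' Convenience pipeline: Kirchhoff matrix, eigendecomposition, fast-mode
#' energy response plus full-spectrum mean-square fluctuations and predicted
#' B-factors.
#'
#' @param trace a [calpha_trace()].
#' @param params an [enm_params()] bundle; `params$mode_selection` governs
#'   the energy-response column, while `msf`/`b_pred` always use all
#'   nonzero modes.
#' @return A `response_profile` (see [energy_response_profile()]).
#' @export
enm_profile <- function(trace, params = enm_params()) {
  K <- build_kirchhoff(trace, params)
  sp <- eigendecompose(K)
  full <- mode_restricted_inverse(sp, "all-nonzero", kT = params$kT)
  ms <- parse_mode_selection(params$mode_selection)
  n_nonzero <- length(sp$values) - sp$n_zero_modes
  if (!identical(ms$type, "all-nonzero") && ms$k > n_nonzero) {
    warning("mode selection ", params$mode_selection, " capped at the ",
            n_nonzero, " available nonzero mode(s)")
    ms$k <- n_nonzero
  }
  sel <- if (identical(ms$type, "all-nonzero")) full
         else mode_restricted_inverse(sp, paste0(ms$type, ":", ms$k),
                                      kT = params$kT)
  energy_response_profile(sel, K, corr_full = full)
}

#' Write a response profile as tab-separated text
#'
#' Columns `chain, resnum, aa, msf, b_pred, b_exp, energy_response` plus
#' `is_peak` when a peak set is supplied.
#'
#' @param profile a `response_profile`.
#' @param path output file.
#' @param peaks optional `peak_set` from [detect_peaks()].
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, peaks = NULL) {
  df <- as.data.frame(profile)[, c("chain", "resnum", "aa", "msf", "b_pred",
                                   "b_exp", "energy_response")]
  df$is_peak <- if (is.null(peaks)) FALSE
                else profile$resnum %in% peaks$members
  utils::write.table(format(df, digits = 15, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
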