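#' Tile a sequence into overlapping fixed-length peptides
#'
#' Slides a window of width `k` along the sequence one residue at a time:
#' the first peptide covers residues 1..k, the second 2..k+1, and so on,
#' giving `n - k + 1` peptides for an n-residue source — e.g. a 336-residue
#' chain yields 331 hexapeptides. When tiling a [calpha_trace()], windows
#' that would bridge a gap in the author residue numbering are dropped
#' (missing residues break contiguity rather than being silently spliced).
#'
#' @param x one-letter sequence string, or a [calpha_trace()].
#' @param k window length (>= 2); default 6 (hexapeptides).
#' @param source label recorded with each peptide.
#'
#' @return Data frame of class `peptide_library` with columns `peptide`,
#'   `start`, `end`, `source`. `start`/`end` are 1-based sequence positions
#'   for a string input, author residue numbers for a trace.
#' @export
#' @examples
#' tile_peptides("ABCDEFG", k = 6)
tile_peptides <- function(x, k = 6L, source = "seq") {
  k <- as.integer(k)
  if (k < 2L) stop("window length k must be >= 2")
  if (inherits(x, "calpha_trace")) {
    letters1 <- x$one_letter
    numbers <- x$resnum
    if (missing(source)) source <- paste0("chain_", x$chain[1L])
  } else {
    s <- as.character(x)
    stopifnot(length(s) == 1L)
    letters1 <- strsplit(s, "")[[1L]]
    numbers <- seq_along(letters1)
  }
  n <- length(letters1)
  if (n < k) stop("sequence length (", n, ") shorter than window k = ", k)
  starts <- seq_len(n - k + 1L)
  contiguous <- vapply(starts, function(i) {
    all(diff(numbers[i:(i + k - 1L)]) == 1L)
  }, logical(1))
  if (!all(contiguous))
    warning(sum(!contiguous),
            " window(s) dropped across gaps in residue numbering")
  starts <- starts[contiguous]
  out <- data.frame(
    peptide = vapply(starts, function(i)
      paste(letters1[i:(i + k - 1L)], collapse = ""), character(1)),
    start = numbers[starts],
    end = numbers[starts + k - 1L],
    source = source,
    stringsAsFactors = FALSE
  )
  class(out) <- c("peptide_library", "data.frame")
  out
}

#' Extract a peptide by residue range
#'
#' @param x a [calpha_trace()] (resolved by author residue numbering) or a
#'   one-letter sequence string (1-based positions).
#' @param start,end inclusive residue range, `start <= end`.
#' @param source label for the returned record.
#' @return One-row `peptide_library` data frame. Missing residues inside the
#'   range raise an error naming the gap.
#' @export
peptide_at <- function(x, start, end, source = "seq") {
  if (start > end) stop("start (", start, ") exceeds end (", end, ")")
  if (inherits(x, "calpha_trace")) {
    if (missing(source)) source <- paste0("chain_", x$chain[1L])
    want <- seq.int(start, end)
    ix <- match(want, x$resnum)
    if (anyNA(ix))
      stop("residue range ", start, "-", end, " not fully present; missing: ",
           paste(want[is.na(ix)], collapse = ", "))
    seqc <- paste(x$one_letter[ix], collapse = "")
  } else {
    s <- strsplit(as.character(x), "")[[1L]]
    if (start < 1L || end > length(s))
      stop("range ", start, "-", end, " outside sequence of length ",
           length(s))
    seqc <- paste(s[start:end], collapse = "")
  }
  out <- data.frame(peptide = seqc, start = as.integer(start),
                    end = as.integer(end), source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_library", "data.frame")
  out
}

# molar gas constant, J / (mol K)
GAS_CONSTANT <- 8.314462618

#' Binding free energy record
#'
#' @param delta_a binding free energy in kJ/mol (negative = favourable).
#' @param temperature absolute temperature in Kelvin; default 310 K
#'   (physiological).
#' @return List of class `binding_energy`.
#' @export
binding_energy <- function(delta_a, temperature = 310) {
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  structure(list(delta_a = delta_a, temperature = temperature),
            class = "binding_energy")
}

#' Convert a binding free energy to a dissociation constant
#'
#' `k_D = exp(dA / (R T))` with `dA` in kJ/mol, `R` the molar gas constant
#' and the standard-state 1 M reference: a -49 kJ/mol binder at 310 K has
#' `k_D` of about 5.5 nM.
#'
#' @param be a [binding_energy()], or a numeric `delta_a` in kJ/mol.
#' @param temperature Kelvin, used when `be` is numeric.
#' @return Dissociation constant in molar units, with attribute `pretty`
#'   giving a human-readable string (nM below 1 uM, etc.).
#' @export
#' @examples
#' dissociation_constant(-49)           # ~5.5e-9 M
dissociation_constant <- function(be, temperature = 310) {
  if (!inherits(be, "binding_energy")) be <- binding_energy(be, temperature)
  kd <- exp(be$delta_a * 1000 / (GAS_CONSTANT * be$temperature))
  attr(kd, "pretty") <- format_kd(kd)
  kd
}

#' @rdname dissociation_constant
#' @param kd dissociation constant in molar units.
#' @export
format_kd <- function(kd) {
  kd <- as.numeric(kd)
  ifelse(kd < 1e-9, sprintf("%.3g pM", kd * 1e12),
  ifelse(kd < 1e-6, sprintf("%.3g nM", kd * 1e9),
  ifelse(kd < 1e-3, sprintf("%.3g uM", kd * 1e6),
  ifelse(kd < 1,    sprintf("%.3g mM", kd * 1e3),
                    sprintf("%.3g M", kd)))))
}

#' Free energy implied by a dissociation constant
#'
#' Inverse of [dissociation_constant()]: `dA = R T ln(k_D)` in kJ/mol.
#'
#' @param kd dissociation constant, molar.
#' @param temperature Kelvin.
#' @return Free energy in kJ/mol.
#' @export
binding_energy_from_kd <- function(kd, temperature = 310) {
  GAS_CONSTANT * temperature * log(kd) / 1000
}

#' Write a peptide library as FASTA
#'
#' One record per peptide with header `source|start-end`
#' (e.g. `>2JDV_A|318-323`); round-trips through any FASTA reader.
#'
#' @param library a `peptide_library`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  stopifnot(inherits(library, "peptide_library"), nrow(library) >= 1L)
  seqs <- Biostrings::AAStringSet(library$peptide)
  names(seqs) <- sprintf("%s|%d-%d", library$source, library$start,
                         library$end)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read externally produced docking scores and rank by affinity
#'
#' Reads a tab-separated table of peptide identifiers and docking energies
#' (kJ/mol), attaches the implied dissociation constants, and sorts from the
#' strongest binder (most negative energy, smallest k_D) down.
#'
#' @param path TSV with columns `peptide` (or any id column first) and
#'   `score` in kJ/mol.
#' @param temperature Kelvin for the k_D conversion.
#' @return Data frame sorted by `kd` ascending with columns `peptide`,
#'   `score`, `kd`, `kd_pretty`.
#' @export
read_docking_scores <- function(path, temperature = 310) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("peptide", "score")
  df$kd <- vapply(df$score, function(s)
    as.numeric(dissociation_constant(s, temperature)), numeric(1))
  df$kd_pretty <- format_kd(df$kd)
  df[order(df$kd), , drop = FALSE]
}
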