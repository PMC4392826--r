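#' Construct a C-alpha trace
#'
#' A `calpha_trace` is an ordered per-residue table: one C-alpha atom per
#' residue with its coordinates and (optionally) the crystallographic
#' B-factor. It is the input container for all elastic-network calculations.
#'
#' @param chain chain identifier(s), recycled to length `n`.
#' @param resnum author residue numbers (integer).
#' @param icode insertion codes (`""` when absent), recycled.
#' @param aa three-letter residue codes (e.g. `"ALA"`).
#' @param x,y,z C-alpha coordinates in Angstrom.
#' @param b experimental B-factors in Angstrom^2, or `NA` when absent.
#'
#' @return A data frame of class `calpha_trace` with columns
#'   `chain, resnum, icode, aa, one_letter, x, y, z, b`.
#' @export
#' @examples
#' tr <- calpha_trace(resnum = 1:3, aa = c("MET", "GLY", "ASN"),
#'                    x = c(0, 3.8, 7.6), y = 0, z = 0)
#' extract_sequence(tr)
calpha_trace <- function(chain = "A", resnum, icode = "", aa, x, y, z,
                         b = NA_real_) {
  n <- length(resnum)
  df <- data.frame(
    chain = rep_len(as.character(chain), n),
    resnum = as.integer(resnum),
    icode = rep_len(as.character(icode), n),
    aa = rep_len(toupper(as.character(aa)), n),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    b = rep_len(as.numeric(b), n),
    stringsAsFactors = FALSE
  )
  df$one_letter <- aa_three_to_one(df$aa)
  new_calpha_trace(df[, c("chain", "resnum", "icode", "aa", "one_letter",
                          "x", "y", "z", "b")])
}

new_calpha_trace <- function(df) {
  key <- paste(df$chain, df$resnum, df$icode)
  if (anyDuplicated(key))
    stop("duplicate (chain, resnum, icode) keys in C-alpha trace: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite C-alpha coordinates")
  rownames(df) <- NULL
  class(df) <- c("calpha_trace", "data.frame")
  df
}

#' @export
print.calpha_trace <- function(x, ...) {
  cat(sprintf("C-alpha trace: %d residues, chain(s) %s, residues %d-%d\n",
              nrow(x), paste(unique(x$chain), collapse = ","),
              min(x$resnum), max(x$resnum)))
  if (all(is.na(x$b))) cat("  experimental B-factors: absent\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more residues\n")
  invisible(x)
}

# coordinate matrix (n x 3) of a trace
trace_coords <- function(trace) {
  as.matrix(as.data.frame(trace)[, c("x", "y", "z")])
}

# residue display labels: resnum plus insertion code when present
residue_labels <- function(trace) {
  paste0(trace$resnum, ifelse(trace$icode == "" | is.na(trace$icode),
                              "", trace$icode))
}

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

aa_three_to_one <- function(aa) {
  out <- unname(THREE_TO_ONE[toupper(aa)])
  out[is.na(out)] <- "X"
  out
}

#' Read a C-alpha trace from a PDB file
#'
#' Parses wwPDB-format coordinates (via [bio3d::read.pdb()]) and reduces them
#' to one C-alpha entry per residue. Only `ATOM` records with atom name `CA`
#' are kept; `HETATM` records (waters, ligands) are ignored; for NMR-style
#' multi-model files only the first model is used; alternate locations keep
#' the blank or `'A'` altloc and discard the rest. Residues present in the
#' chain but lacking a C-alpha are skipped with a warning.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @param chain chain identifier to extract. When `NULL` and the file has a
#'   single chain, that chain is used; otherwise an error lists the
#'   available chains.
#'
#' @return A [calpha_trace()] with author residue numbering and the B-factor
#'   column captured.
#' @export
read_calpha_trace <- function(pdb, chain = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1L], fixed = TRUE) ||
      !file.exists(pdb[1L])) {
    if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) &&
        !grepl("^ATOM|^HETATM|^HEADER|^MODEL|^REMARK", pdb))
      stop("file not found: ", pdb)
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  }
  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found in PDB input")
  at$insert[is.na(at$insert)] <- ""
  available <- unique(at$chain)
  if (is.null(chain)) {
    if (length(available) > 1L)
      stop("multiple chains present (", paste(available, collapse = ", "),
           "); specify `chain`")
    chain <- available
  }
  if (!chain %in% available)
    stop("chain '", chain, "' not found; available chains: ",
         paste(available, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]

  res_key <- paste(at$resno, at$insert)
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(unique(res_key), paste(ca$resno, ca$insert))
  if (length(missing_ca) > 0L)
    warning(length(missing_ca), " residue(s) without a CA atom skipped: ",
            paste(missing_ca, collapse = ", "))
  # residues appear in file order; keep the first CA should duplicates survive
  ca_key <- paste(ca$resno, ca$insert)
  if (anyDuplicated(ca_key)) {
    warning("duplicate CA atoms for a residue; keeping the first occurrence")
    ca <- ca[!duplicated(ca_key), , drop = FALSE]
  }
  calpha_trace(chain = chain, resnum = ca$resno, icode = ca$insert,
               aa = ca$resid, x = ca$x, y = ca$y, z = ca$z, b = ca$b)
}

#' Extract the one-letter sequence of a trace
#'
#' @param trace a [calpha_trace()].
#' @return Single string; nonstandard residues map to `"X"`.
#' @export
extract_sequence <- function(trace) {
  stopifnot(inherits(trace, "calpha_trace"), nrow(trace) >= 1L)
  paste(trace$one_letter, collapse = "")
}

#' Generate a synthetic C-alpha trace
#'
#' Test-fixture generator producing toy backbones with known contact
#' topology: a straight chain at fixed spacing, an ideal alpha-helical
#' C-alpha coil (rise 1.5 A per residue, 100 degrees per turn, radius
#' 2.3 A), or points of a cubic lattice. Optional isotropic Gaussian noise
#' perturbs each coordinate. Deterministic under `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param n_residues number of residues (>= 2).
#' @param geometry one of `"linear"`, `"helix"`, `"perturbed-lattice"`.
#' @param spacing inter-residue spacing in Angstrom (linear and lattice
#'   geometries); default 3.8, the canonical CA-CA virtual bond length.
#' @param noise_sd standard deviation (Angstrom) of Gaussian coordinate
#'   noise; 0 gives exact geometry.
#' @param seed integer seed controlling the noise.
#' @param b_factors optional vector of synthetic experimental B-factors.
#'
#' @return A [calpha_trace()] of poly-alanine with residues numbered 1..n.
#' @export
#' @examples
#' generate_synthetic_trace(5, "linear", noise_sd = 0)
generate_synthetic_trace <- function(n_residues,
                                     geometry = c("linear", "helix",
                                                  "perturbed-lattice"),
                                     spacing = 3.8, noise_sd = 0,
                                     seed = 1L, b_factors = NULL) {
  geometry <- match.arg(geometry)
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  i <- seq_len(n_residues) - 1L
  coords <- switch(geometry,
    linear = cbind(i * spacing, 0, 0),
    helix = {
      theta <- i * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), i * 1.5)
    },
    `perturbed-lattice` = {
      side <- ceiling(n_residues^(1 / 3))
      gx <- i %% side
      gy <- (i %/% side) %% side
      gz <- i %/% (side * side)
      cbind(gx, gy, gz) * spacing
    }
  )
  if (noise_sd > 0) {
    coords <- coords + with_seed(seed, {
      matrix(stats::rnorm(3L * n_residues, sd = noise_sd),
             ncol = 3L)
    })
  }
  calpha_trace(chain = "A", resnum = seq_len(n_residues), aa = "ALA",
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               b = if (is.null(b_factors)) NA_real_ else b_factors)
}

#' Generate a trace with planted high-flexibility loci
#'
#' Builds an ideal alpha-helical C-alpha coil and pushes short segments
#' radially outward with a Gaussian-shaped displacement centred on each
#' planted locus. The pushed segments keep their chain contacts but lose
#' most packing contacts against the helix body, so they fluctuate more than
#' the rest of the structure; the energy-response profile develops peak
#' regions at and around the planted loci. Used as ground truth for peak
#' detection and conservation-overlap tests.
#'
#' @param n_residues chain length.
#' @param loci residue numbers of the planted flexible loci.
#' @param amplitude maximum radial displacement in Angstrom.
#' @param width Gaussian width (residues) of each displacement bump.
#' @param noise_sd isotropic coordinate noise (Angstrom).
#' @param seed integer seed.
#' @return A [calpha_trace()] with attribute `planted_loci`.
#' @export
generate_planted_trace <- function(n_residues = 80, loci = c(25, 60),
                                   amplitude = 3, width = 1.5,
                                   noise_sd = 0.15, seed = 1L) {
  stopifnot(all(loci >= 1), all(loci <= n_residues), amplitude >= 0)
  tr <- generate_synthetic_trace(n_residues, "helix", noise_sd = noise_sd,
                                 seed = seed)
  i <- seq_len(n_residues)
  push <- rowSums(vapply(loci, function(c0)
    amplitude * exp(-(i - c0)^2 / (2 * width^2)), numeric(n_residues)))
  r <- sqrt(tr$x^2 + tr$y^2)
  tr$x <- tr$x * (r + push) / r
  tr$y <- tr$y * (r + push) / r
  attr(tr, "planted_loci") <- loci
  tr
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Write / read a trace as tab-separated text
#'
#' Plain-text serialization (`chain, resnum, icode, aa, x, y, z, b`) used by
#' the reporting pipeline; round-trips exactly at full double precision.
#'
#' @param trace a [calpha_trace()].
#' @param path output (input) file path.
#' @return `write_trace_tsv` returns `path` invisibly; `read_trace_tsv`
#'   returns a [calpha_trace()].
#' @export
write_trace_tsv <- function(trace, path) {
  df <- as.data.frame(trace)[, c("chain", "resnum", "icode", "aa",
                                 "x", "y", "z", "b")]
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chain = "character",
                                         icode = "character",
                                         aa = "character"),
                          na.strings = "NA")
  df$icode[is.na(df$icode)] <- ""
  calpha_trace(chain = df$chain, resnum = df$resnum, icode = df$icode,
               aa = df$aa, x = df$x, y = df$y, z = df$z, b = df$b)
}

#' Write a trace's sequence as FASTA
#'
#' @param trace a [calpha_trace()].
#' @param path output file.
#' @param id record identifier; defaults to `chain` of the trace.
#' @return `path`, invisibly.
#' @export
write_sequence_fasta <- function(trace, path, id = NULL) {
  if (is.null(id)) id <- paste0("chain_", trace$chain[1L])
  seqs <- Biostrings::AAStringSet(extract_sequence(trace))
  names(seqs) <- id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
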