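#' Detect energy-response peaks (hotspot regions)
#'
#' A residue qualifies when its energy response exceeds
#' `mean(dU) + z * sd(dU)` and it is a local maximum of the profile along
#' the sequence; runs of adjacent qualifying residues merge into one hotspot
#' region, reported by the residue at its maximum (the region center).
#' Because both the threshold and local-maximum tests compare values on the
#' same profile, peak calls are invariant under any positive rescaling of
#' the profile — consistent with the arbitrary units of the energy response.
#'
#' @param profile a `response_profile` from [energy_response_profile()], or
#'   a bare numeric vector of per-residue responses.
#' @param z threshold multiplier (default 1: one standard deviation above
#'   the mean).
#'
#' @return List of class `peak_set`: `centers` (author residue numbers of
#'   region maxima), `members` (all residues in any region), `regions`
#'   (list of per-region member vectors), `threshold` and `z`. A constant
#'   profile yields an empty peak set.
#' @export
#' @examples
#' du <- c(rep(1, 9), 10, rep(1, 10))
#' detect_peaks(du)$centers  # residue 10
detect_peaks <- function(profile, z = 1) {
  if (inherits(profile, "response_profile")) {
    du <- profile$energy_response
    resnum <- profile$resnum
  } else {
    du <- as.numeric(profile)
    resnum <- seq_along(du)
  }
  n <- length(du)
  if (n == 0L) stop("empty profile")
  thr <- mean(du) + z * stats::sd(du)
  if (!is.finite(thr)) thr <- mean(du)          # single-residue profile
  above <- du > thr
  # local maximum along the sequence (ties count; endpoints use one side)
  left <- c(-Inf, du[-n])
  right <- c(du[-1L], -Inf)
  local_max <- du >= left & du >= right
  if (!any(above))
    return(structure(list(centers = integer(0), members = integer(0),
                          regions = list(), threshold = thr, z = z),
                     class = "peak_set"))
  # maximal runs of consecutive above-threshold residues form regions
  run_id <- cumsum(c(TRUE, diff(which(above)) > 1L))
  idx_above <- which(above)
  regions <- split(idx_above, run_id)
  # region must contain a sequence-local maximum; center = region argmax
  keep <- vapply(regions, function(ix) any(local_max[ix]), logical(1))
  regions <- regions[keep]
  centers <- vapply(regions, function(ix) ix[which.max(du[ix])], integer(1))
  members_idx <- sort(unlist(regions, use.names = FALSE))
  structure(list(centers = unname(resnum[centers]),
                 members = resnum[members_idx],
                 regions = unname(lapply(regions, function(ix) resnum[ix])),
                 threshold = thr, z = z),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d region(s), threshold %.4g (z = %g)\n",
              length(x$regions), x$threshold, x$z))
  for (i in seq_along(x$regions))
    cat(sprintf("  region %d: center %s, members %s\n", i, x$centers[i],
                paste(x$regions[[i]], collapse = ",")))
  invisible(x)
}

#' Build the residue contact graph
#'
#' Undirected graph with one vertex per residue (named by author residue
#' number plus insertion code) and an edge wherever the CA-CA distance is at
#' most `cutoff` — the same contact rule as the Kirchhoff matrix.
#'
#' @param trace a [calpha_trace()].
#' @param cutoff contact distance in Angstrom.
#' @return An [igraph][igraph::graph_from_adjacency_matrix] object with
#'   vertex attributes `resnum`, `aa`, `x`, `y`, `z` and edge attribute
#'   `distance`.
#' @export
build_contact_graph <- function(trace, cutoff = 7.0) {
  stopifnot(inherits(trace, "calpha_trace"), nrow(trace) >= 2L)
  xyz <- trace_coords(trace)
  d <- as.matrix(stats::dist(xyz))
  A <- (d <= cutoff) * 1
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- residue_labels(trace)
  igraph::V(g)$resnum <- trace$resnum
  igraph::V(g)$aa <- trace$one_letter
  igraph::V(g)$x <- trace$x
  igraph::V(g)$y <- trace$y
  igraph::V(g)$z <- trace$z
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$distance <- d[el]
  g
}

# resolve a residue query (number, "77A", "ALA77", "R176") to a vertex name
resolve_residue <- function(graph, query) {
  nm <- igraph::V(graph)$name
  q <- toupper(trimws(as.character(query)))
  if (q %in% nm) return(q)
  m <- regmatches(q, regexec("^([A-Z]{1,3})?([0-9]+[A-Z]?)$", q))[[1L]]
  if (length(m) > 0L && m[3L] %in% nm) {
    v <- m[3L]
    aa_q <- m[2L]
    if (nzchar(aa_q)) {
      aa_v <- igraph::V(graph)$aa[match(v, nm)]
      one <- if (nchar(aa_q) == 3L) aa_three_to_one(aa_q) else aa_q
      if (!identical(one, aa_v))
        stop("residue ", v, " is ", aa_v, ", not ", aa_q,
             " as given in query '", query, "'")
    }
    return(v)
  }
  stop("residue '", query, "' not found in structure")
}

#' Extract the shortest contact path between two residues
#'
#' Shortest path by hop count on the contact graph; ties are broken by the
#' smallest total Euclidean CA-CA length, then by lexicographic residue
#' order. The search can be restricted to a residue subset (e.g. detected
#' peaks) plus the two endpoints, which extracts the energy-conduction path
#' running through hotspot residues. Disconnected endpoints give an explicit
#' no-path result rather than an error.
#'
#' @param graph contact graph from [build_contact_graph()].
#' @param source,target residue queries: author numbers (`77`), labels with
#'   insertion codes, or amino-acid-prefixed tokens (`"ALA77"`, `"R176"`).
#' @param restrict_to optional vector of residue queries; the path is
#'   confined to these residues plus the endpoints.
#'
#' @return List of class `residue_path`: `found`, `residues` (ordered vertex
#'   labels), `aa` (one-letter codes), `hops`, `step_distances` (Angstrom).
#' @export
extract_path <- function(graph, source, target, restrict_to = NULL) {
  s <- resolve_residue(graph, source)
  t <- resolve_residue(graph, target)
  g <- graph
  if (!is.null(restrict_to)) {
    allow <- unique(c(vapply(restrict_to, function(q)
      resolve_residue(graph, q), character(1)), s, t))
    g <- igraph::induced_subgraph(graph, allow)
  }
  no_path <- structure(list(found = FALSE, residues = character(0),
                            aa = character(0), hops = NA_integer_,
                            step_distances = numeric(0),
                            source = s, target = t),
                       class = "residue_path")
  if (igraph::distances(g, v = s, to = t)[1, 1] == Inf) return(no_path)
  asp <- igraph::all_shortest_paths(g, from = s, to = t)$vpaths
  cand <- lapply(asp, function(p) igraph::V(g)$name[as.integer(p)])
  lens <- vapply(cand, function(p) path_length(g, p), numeric(1))
  best <- which(lens == min(lens))
  if (length(best) > 1L) {               # lexicographic on the label sequence
    keys <- vapply(cand[best], paste, character(1), collapse = "\r")
    best <- best[order(keys)][1L]
  }
  p <- cand[[best[1L]]]
  structure(list(found = TRUE, residues = p,
                 aa = igraph::V(g)$aa[match(p, igraph::V(g)$name)],
                 hops = length(p) - 1L,
                 step_distances = step_dists(g, p),
                 source = s, target = t),
            class = "residue_path")
}

path_length <- function(g, p) sum(step_dists(g, p))

step_dists <- function(g, p) {
  if (length(p) < 2L) return(numeric(0))
  ix <- match(p, igraph::V(g)$name)
  xyz <- cbind(igraph::V(g)$x, igraph::V(g)$y, igraph::V(g)$z)[ix, ,
                                                               drop = FALSE]
  sqrt(rowSums(diff(xyz)^2))
}

#' @export
print.residue_path <- function(x, ...) {
  if (!x$found) {
    cat("No contact path between", x$source, "and", x$target, "\n")
  } else {
    cat(sprintf("Path %s -> %s: %d hops\n  %s\n", x$source, x$target, x$hops,
                paste(paste0(x$aa, x$residues), collapse = " -> ")))
  }
  invisible(x)
}

#' Read a residue conservation table
#'
#' Two-column tab-separated input: author residue number and conservation
#' level on the 1-8 scale (8 = most conserved).
#'
#' @param path TSV file with columns `resnum` and `level` (header optional).
#' @return Data frame of class `conservation_table`.
#' @export
read_conservation <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  df <- if (header) utils::read.table(path, header = TRUE, sep = "\t")
        else utils::read.table(path, header = FALSE, sep = "\t",
                               col.names = c("resnum", "level"))
  names(df)[1:2] <- c("resnum", "level")
  conservation_table(df$resnum, df$level)
}

#' @rdname read_conservation
#' @param resnum author residue numbers.
#' @param level integer conservation levels in `[1, 8]`.
#' @export
conservation_table <- function(resnum, level) {
  level <- as.integer(level)
  if (any(level < 1L | level > 8L, na.rm = TRUE))
    stop("conservation levels must lie in [1, 8]")
  structure(data.frame(resnum = as.integer(resnum), level = level),
            class = c("conservation_table", "data.frame"))
}

#' Overlap between conserved residues and energy-response peaks
#'
#' Measures how much the most conserved residues coincide with the detected
#' hotspot residues: the fraction of residues at conservation level >=
#' `level` that are peak members or contact-graph neighbours of a peak
#' member (graph adjacency at the ENM cutoff is the C-alpha-level proxy for
#' "in the neighbourhood of the path"). Significance comes from a
#' permutation test that re-assigns the conserved labels uniformly at random
#' over all residues; this statistic is an addition of this package — the
#' underlying claim of hotspot/conservation correlation is qualitative.
#'
#' @param peaks a `peak_set` from [detect_peaks()].
#' @param cons a `conservation_table`; entries whose residue numbers do not
#'   match the structure are dropped with a warning.
#' @param graph contact graph from [build_contact_graph()].
#' @param level minimum conservation level counted as "conserved"
#'   (default 8, the top ConSurf-style grade).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation draw.
#'
#' @return List of class `conservation_overlap`: `fraction` (observed
#'   overlap, `NA` with `undefined = TRUE` when no residue reaches
#'   `level`), `p_value` (one-sided permutation p, `(1 + #{perm >= obs}) /
#'   (n_permutations + 1)`), `n_conserved`, `n_hot`, `level`,
#'   `n_permutations`, `seed`.
#' @export
conservation_overlap <- function(peaks, cons, graph, level = 8L,
                                 n_permutations = 999L, seed = 1L) {
  stopifnot(inherits(peaks, "peak_set"),
            inherits(cons, "conservation_table"),
            level >= 1L, level <= 8L, n_permutations >= 1L)
  vn <- igraph::V(graph)$name
  resnum_v <- igraph::V(graph)$resnum
  unmatched <- !(cons$resnum %in% resnum_v)
  if (any(unmatched)) {
    warning(sum(unmatched), " conservation entries not in structure dropped: ",
            paste(cons$resnum[unmatched], collapse = ", "))
    cons <- cons[!unmatched, , drop = FALSE]
  }
  if (nrow(cons) == 0L) stop("no conservation entries match the structure")
  # hot set: peak members and their graph neighbours
  peak_v <- vn[resnum_v %in% peaks$members]
  hot <- peak_v
  if (length(peak_v) > 0L)
    hot <- unique(c(peak_v, igraph::V(graph)$name[
      unlist(igraph::adjacent_vertices(graph, peak_v))]))
  hot_resnum <- resnum_v[match(hot, vn)]
  conserved <- cons$resnum[cons$level >= level]
  n_cons <- length(conserved)
  if (n_cons == 0L)
    return(structure(list(fraction = NA_real_, undefined = TRUE,
                          p_value = NA_real_, n_conserved = 0L,
                          n_hot = length(hot), level = level,
                          n_permutations = n_permutations, seed = seed),
                     class = "conservation_overlap"))
  obs <- mean(conserved %in% hot_resnum)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      mean(sample(resnum_v, n_cons) %in% hot_resnum)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_permutations + 1)
  structure(list(fraction = obs, undefined = FALSE, p_value = p,
                 n_conserved = n_cons, n_hot = length(hot), level = level,
                 n_permutations = n_permutations, seed = seed,
                 null_fractions = perm),
            class = "conservation_overlap")
}

#' @export
print.conservation_overlap <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("Conservation overlap: no residues at level >=", x$level, "\n")
  } else {
    cat(sprintf(paste0(
      "Conservation overlap: %.3f of %d level->=%d residues are peaks or\n",
      "  peak-adjacent (%d hot residues); permutation p = %.4g (%d draws)\n"),
      x$fraction, x$n_conserved, x$level, x$n_hot, x$p_value,
      x$n_permutations))
  }
  invisible(x)
}
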