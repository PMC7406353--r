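#' Probabilistic atlas from per-subject area label maps
#'
#' Per vertex and per area, counts the number of subjects whose label at that
#' vertex equals the area. Labels are user-supplied strings; the reserved
#' label `"none"` (and `NA`) means unlabeled.
#'
#' @param labels List of per-vertex label vectors (character or factor), all
#'   on the same mesh.
#' @return A `prob_atlas` with `counts` (vertex x area matrix), `areas` and
#'   `n_subjects`.
#' @export
probabilistic_map <- function(labels) {
  stopifnot(length(labels) >= 1L)
  labels <- lapply(labels, as.character)
  nv <- length(labels[[1]])
  for (s in seq_along(labels))
    if (length(labels[[s]]) != nv)
      stop("label maps are not on the same mesh")
  areas <- sort(setdiff(unique(unlist(labels)), c("none", NA)))
  counts <- matrix(0L, nv, length(areas), dimnames = list(NULL, areas))
  for (s in seq_along(labels)) {
    for (a in areas) counts[, a] <- counts[, a] + (labels[[s]] == a)
  }
  structure(list(counts = counts, areas = areas,
                 n_subjects = length(labels)),
            class = "prob_atlas")
}

#' Normalized overlap histogram of one atlas area
#'
#' Frequencies of the overlap levels 1..N (number of subjects labeling a
#' vertex), normalized by the number of vertices with count >= 1 for the
#' area, so the frequencies sum to 1. The left-skew statistic (mass at level
#' 1 minus mass at level N) summarizes how left-skewed the distribution is;
#' better alignment gives less left skew.
#'
#' @param atlas A `prob_atlas`.
#' @param area Area name.
#' @return An `overlap_histogram` with `freq` (length N), `levels`, `area`
#'   and `left_skew`.
#' @export
overlap_histogram <- function(atlas, area) {
  stopifnot(inherits(atlas, "prob_atlas"))
  if (!area %in% atlas$areas)
    stop(sprintf("area '%s' is absent from the atlas", area))
  v <- atlas$counts[, area]
  support <- sum(v >= 1L)
  if (support == 0L)
    stop(sprintf("area '%s' is absent from all subjects", area))
  N <- atlas$n_subjects
  freq <- tabulate(v[v >= 1L], nbins = N) / support
  structure(list(freq = freq, levels = seq_len(N), area = area,
                 left_skew = freq[1] - freq[N]),
            class = "overlap_histogram")
}

#' DICE coefficient of two vertex sets
#'
#' `2 |A intersect B| / (|A| + |B|)`. Sets may be logical masks (same length)
#' or integer index vectors. Two empty sets give 0 with a warning.
#'
#' @param a,b Vertex sets.
#' @return DICE coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    stopifnot(length(a) == length(b))
    na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  } else {
    a <- unique(as.integer(a)); b <- unique(as.integer(b))
    na <- length(a); nb <- length(b); ni <- length(intersect(a, b))
  }
  if (na + nb == 0L) {
    warning("both sets empty; DICE defined as 0")
    return(0)
  }
  2 * ni / (na + nb)
}

#' Leave-one-subject-out DICE table
#'
#' For each left-out subject and each area: build the training atlas from the
#' remaining N-1 subjects, threshold it at `min_overlap` (vertices labeled by
#' at least `min_overlap` of the training subjects), and compute the DICE
#' between that atlas region and the left-out subject's area. Cells where the
#' area is absent from the training subjects are 0 with a warning. The
#' default threshold is 4 (out of 9 training subjects for a 10-subject
#' cohort).
#'
#' @param labels List of N per-vertex label vectors.
#' @param min_overlap Training-atlas overlap threshold, in 1..N-1.
#' @return A `dice_table` data frame: one row per area, one column per
#'   left-out subject, plus `Mean` and `Std.Dev`.
#' @export
loo_dice <- function(labels, min_overlap = 4) {
  N <- length(labels)
  if (N < 2L) stop("need at least 2 subjects")
  if (min_overlap < 1 || min_overlap > N - 1)
    stop("min_overlap must be between 1 and N-1")
  labels <- lapply(labels, as.character)
  areas <- sort(setdiff(unique(unlist(labels)), c("none", NA)))
  subj_names <- if (!is.null(names(labels))) names(labels) else
    sprintf("Sub-%02d", seq_len(N))
  M <- matrix(NA_real_, length(areas), N, dimnames = list(areas, subj_names))
  for (s in seq_len(N)) {
    train <- probabilistic_map(labels[-s])
    for (a in areas) {
      left_out <- labels[[s]] == a
      if (!a %in% train$areas || !any(train$counts[, a] >= min_overlap)) {
        if (any(left_out))
          warning(sprintf("area '%s' absent from training atlas for left-out subject %s",
                          a, subj_names[s]))
        M[a, s] <- 0
        next
      }
      region <- train$counts[, a] >= min_overlap
      M[a, s] <- if (!any(left_out) && !any(region)) {
        warning(sprintf("area '%s' empty in both atlas and subject %s", a,
                        subj_names[s]))
        0
      } else dice(region, left_out)
    }
  }
  df <- as.data.frame(M)
  df$Mean <- rowMeans(M)
  df$Std.Dev <- apply(M, 1, sd)
  structure(df, class = c("dice_table", "data.frame"),
            min_overlap = min_overlap)
}

#' Write a DICE table as CSV (areas x subjects plus Mean, Std.Dev columns)
#' @param tab A `dice_table`.
#' @param path File path.
#' @export
write_dice_csv <- function(tab, path) {
  write.csv(cbind(Area = rownames(tab), as.data.frame(tab)), path,
            row.names = FALSE)
  invisible(path)
}

#' Export atlas counts as per-area CSV
#' @param atlas A `prob_atlas`.
#' @param path File path.
#' @export
write_atlas_csv <- function(atlas, path) {
  df <- data.frame(vertex_index = seq_len(nrow(atlas$counts)) - 1L,
                   atlas$counts, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
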