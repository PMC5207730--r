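# exact assignment on the overlap matrix: exhaustive for small K, greedy above
best_assignment <- function(overlap) {
  n <- max(dim(overlap))
  m <- matrix(0, n, n)
  m[seq_len(nrow(overlap)), seq_len(ncol(overlap))] <- overlap
  if (n <= 8L) {
    perms <- permutations_of(n)
    scores <- vapply(perms, function(p) sum(m[cbind(seq_len(n), p)]),
                     numeric(1L))
    perms[[which.max(scores)]]
  } else {
    # greedy: repeatedly take the largest remaining overlap
    p <- integer(n)
    mm <- m
    for (step in seq_len(n)) {
      ij <- arrayInd(which.max(mm), dim(mm))
      p[ij[1L]] <- ij[2L]
      mm[ij[1L], ] <- -Inf
      mm[, ij[2L]] <- -Inf
    }
    p
  }
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  # insert n into every slot of each (n-1)-permutation
  for (sub in permutations_of(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

#' Match segmentation labels to ground-truth labels
#'
#' Mixture labels are arbitrary; this relabels a segmentation by the
#' maximum-overlap assignment against a ground truth (exhaustive over
#' permutations for up to 8 labels, greedy beyond).
#'
#' @param seg integer label matrix/vector.
#' @param gt ground-truth labels, same shape.
#' @return `seg` relabelled into the ground-truth label set.
#' @export
match_labels <- function(seg, gt) {
  stopifnot(length(seg) == length(gt))
  ks <- sort(unique(as.integer(seg))); kg <- sort(unique(as.integer(gt)))
  n <- max(length(ks), length(kg))
  ov <- matrix(0, length(ks), length(kg))
  tab <- table(factor(as.integer(seg), levels = ks),
               factor(as.integer(gt), levels = kg))
  ov[] <- as.numeric(tab)
  p <- best_assignment(ov)
  # map seg label ks[i] -> gt label kg[p[i]] (padded targets get fresh labels)
  kg_pad <- c(kg, setdiff(seq_len(max(kg) + n), kg))[seq_len(n)]
  map <- kg_pad[p[seq_along(ks)]]
  out <- seg
  out[] <- map[match(as.integer(seg), ks)]
  out
}

#' Correct classification ratio
#'
#' Fraction of pixels assigned to the correct ground-truth class after
#' maximum-overlap label matching; 1 is a perfect segmentation.
#'
#' @param seg segmentation label matrix.
#' @param gt ground-truth label matrix, same shape.
#' @param match relabel `seg` by maximum overlap first (default TRUE).
#' @return value in `[0, 1]`.
#' @export
ccr <- function(seg, gt, match = TRUE) {
  if (!identical(dim(seg), dim(gt)) && length(seg) != length(gt)) {
    stop("shape mismatch between segmentation and ground truth", call. = FALSE)
  }
  if (match) seg <- match_labels(seg, gt)
  mean(as.integer(seg) == as.integer(gt))
}

#' Dice coefficient of two binary masks
#'
#' 2|A intersect B| / (|A| + |B|); symmetric, 1 for identical masks, 0 for
#' disjoint nonempty masks. Two empty masks score 1 by convention (message).
#'
#' @param mask1,mask2 logical/0-1 masks of the same shape.
#' @return value in `[0, 1]`.
#' @export
dice_coef <- function(mask1, mask2) {
  if (length(mask1) != length(mask2)) stop("shape mismatch", call. = FALSE)
  a <- as.logical(mask1); b <- as.logical(mask2)
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("both masks empty: Dice = 1 by convention")
    return(1)
  }
  2 * sum(a & b) / denom
}

# pairwise co-clustering agreement between two labelings, via the
# contingency-table identity (equals the O(N^2) pair loop exactly)
rand_agreement <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  ss <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  tp <- choose(n, 2)
  (tp + 2 * ss - sa - sb) / tp
}

#' Probabilistic Rand index
#'
#' Agreement between a segmentation and a set of ground-truth labelings over
#' all pixel pairs: for each pair, the probability (over ground truths) that
#' its co-clustering relation matches the segmentation's. Computed through
#' the contingency-table identity, which equals the quadratic pair-loop
#' definition exactly.
#'
#' @param seg segmentation label matrix.
#' @param gts a single ground-truth label matrix or a list of them.
#' @return value in `[0, 1]`.
#' @export
pri <- function(seg, gts) {
  if (!is.list(gts)) gts <- list(gts)
  s <- as.integer(seg)
  vals <- vapply(gts, function(g) {
    if (length(g) != length(s)) stop("shape mismatch", call. = FALSE)
    rand_agreement(s, as.integer(g))
  }, numeric(1L))
  mean(vals)
}
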