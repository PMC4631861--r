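#' Assign mother/daughter identity to a centriole focus pair
#'
#' Given the two pre-bleach centriolar foci, the post-bleach recovered
#' focus, and the reference toroid centre (the ring-shaped signal that
#' surrounds only the mother centriole), labels the pre-bleach focus nearer
#' the toroid centre as the mother and the farther one as the daughter, and
#' computes all three focus-to-toroid distances. Input order of the two
#' pre-bleach foci is irrelevant. When the registration `model` is given,
#' all green-channel focus positions are mapped into the reference
#' channel's frame first (the toroid centre is measured in the reference
#' channel and needs no correction).
#'
#' @param prebleach_foci 2 x 2 matrix of the two pre-bleach focus
#'   positions (rows = foci, columns = x, y), um. Fewer than two rows is an
#'   error: the pair must be resolvable.
#' @param postbleach_focus `(x, y)` position of the recovered focus, or
#'   `NULL` when no recovery was measured.
#' @param toroid_center `(x, y)` centre of the reference toroid, um.
#' @param model optional `RegistrationModel` applied to the focus
#'   positions (foci imaged in the non-reference channel).
#' @param noise_floor_um distance-difference scale below which the
#'   mother/daughter call is flagged ambiguous.
#' @return object of class `FociAssignment`: list with `toroid_center_um`,
#'   `mother_focus_um`, `daughter_focus_um`, `postbleach_focus_um`,
#'   `d_mother_um`, `d_daughter_um`, `d_postbleach_um` (NA when no
#'   post-bleach focus), `ambiguous`.
#' @export
assign_foci <- function(prebleach_foci, postbleach_focus, toroid_center,
                        model = NULL, noise_floor_um = 0.02) {
  prebleach_foci <- matrix(as.numeric(prebleach_foci), ncol = 2)
  if (nrow(prebleach_foci) < 2L) {
    stop("unresolved pair: exactly two pre-bleach foci are required")
  }
  if (nrow(prebleach_foci) > 2L) {
    stop("more than two pre-bleach foci supplied")
  }
  stopifnot(length(toroid_center) == 2L)
  correct <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.null(model)) as.numeric(p) else apply_registration(p, model)
  }
  f1 <- correct(prebleach_foci[1, ]); f2 <- correct(prebleach_foci[2, ])
  pb <- correct(postbleach_focus)
  tc <- as.numeric(toroid_center)
  d1 <- sqrt(sum((f1 - tc)^2)); d2 <- sqrt(sum((f2 - tc)^2))
  if (d1 <= d2) {
    mother <- f1; daughter <- f2; dm <- d1; dd <- d2
  } else {
    mother <- f2; daughter <- f1; dm <- d2; dd <- d1
  }
  structure(
    list(toroid_center_um = tc,
         mother_focus_um = mother,
         daughter_focus_um = daughter,
         postbleach_focus_um = pb,
         d_mother_um = dm,
         d_daughter_um = dd,
         d_postbleach_um = if (is.null(pb)) NA_real_ else sqrt(sum((pb - tc)^2)),
         ambiguous = abs(d1 - d2) < noise_floor_um),
    class = "FociAssignment")
}

.box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  c(n = length(x), mean = mean(x), median = q[2], q25 = q[1], q75 = q[3],
    min = min(x), max = max(x))
}

.two_sample_p <- function(x, y, test, n_perm = 10000L) {
  if (length(unique(c(x, y))) == 1L) {
    return(list(p = NA_real_, note = "degenerate: all values equal; test skipped"))
  }
  p <- switch(test,
    wilcox = stats::wilcox.test(x, y, exact = FALSE)$p.value,
    welch = stats::t.test(x, y)$p.value,
    permutation = {
      obs <- abs(mean(x) - mean(y))
      pooled <- c(x, y); nx <- length(x)
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pooled), nx)
        abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
      }, logical(1)))
      (hits + 1) / (n_perm + 1)
    },
    stop("unknown test: ", test))
  list(p = p, note = NA_character_)
}

#' Compare focus-to-toroid distance groups
#'
#' Box-plot summaries (boxes = 25th-75th percentiles, whiskers = min-max,
#' median line, mean) for the mother, daughter and post-bleach distance
#' groups, plus two-sided pairwise tests of the post-bleach group against
#' each pre-bleach group. The default test is the Mann-Whitney U
#' (distances are non-negative and potentially skewed); Welch's t and a
#' permutation test of the mean difference are available, and the test
#' used is always recorded.
#'
#' @param d_mother,d_daughter,d_postbleach numeric distance vectors, um
#'   (each of length >= 2).
#' @param test `"wilcox"`, `"welch"` or `"permutation"`.
#' @param n_perm permutation count when `test = "permutation"`.
#' @return object of class `GroupComparison`: list with `summary` (one row
#'   per group: n, mean, median, q25, q75, min, max), `pairwise`
#'   (comparison, p_value, note), `test_name`.
#' @export
compare_distance_groups <- function(d_mother, d_daughter, d_postbleach,
                                    test = c("wilcox", "welch", "permutation"),
                                    n_perm = 10000L) {
  test <- match.arg(test)
  groups <- list(mother = d_mother, daughter = d_daughter,
                 postbleach = d_postbleach)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each distance group needs n >= 2")
  }
  summ <- do.call(rbind, lapply(groups, .box_stats))
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL)
  pm <- .two_sample_p(groups$postbleach, groups$mother, test, n_perm)
  pd <- .two_sample_p(groups$postbleach, groups$daughter, test, n_perm)
  structure(
    list(summary = summ,
         pairwise = data.frame(
           comparison = c("postbleach_vs_mother", "postbleach_vs_daughter"),
           p_value = c(pm$p, pd$p),
           note = c(pm$note, pd$note)),
         test_name = switch(test,
                            wilcox = "two-sided Mann-Whitney U",
                            welch = "two-sided Welch t",
                            permutation = "two-sided permutation (mean difference)")),
    class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("GroupComparison (", x$test_name, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
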