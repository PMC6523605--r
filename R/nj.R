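#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with a deterministic tie-break: when several
#' pairs minimize the Q criterion, the pair whose sorted label pair sorts
#' first is joined. Additive distance matrices are recovered exactly (path
#' lengths between tips equal the input distances).
#'
#' @param d symmetric numeric matrix with zero diagonal, n >= 3.
#' @param labels tip labels (default rownames of `d`).
#' @return list of class `nj_tree`: `newick` (semicolon-terminated string)
#'   and `tree` (an [ape::read.tree()] phylo object).
#' @export
build_nj_tree <- function(d, labels = rownames(d)) {
  assert_that(is.matrix(d) && nrow(d) == ncol(d), "`d` must be square")
  n <- nrow(d)
  assert_that(n >= 3, "neighbor joining needs at least 3 taxa")
  assert_that(max(abs(d - t(d))) < 1e-9, "`d` must be symmetric")
  assert_that(all(abs(diag(d)) < 1e-12), "`d` must have a zero diagonal")
  labels <- labels %||% paste0("t", seq_len(n))
  assert_that(length(labels) == n && !anyDuplicated(labels),
              "labels must be unique and match the matrix dimension")
  # working state: subtree newick fragments and the label used for ordering
  sub <- labels
  lab <- labels
  dm <- d
  fmt <- function(x) sprintf("%.10g", x)
  while (length(sub) > 3L) {
    r <- nrow(dm)
    rs <- rowSums(dm)
    q <- (r - 2) * dm - outer(rs, rs, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(lab[ij[1]], lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- dm[i, j] - bi
    merged <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(bi), sub[j], fmt(bj))
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    sub <- c(sub[keep], merged)
    lab <- c(lab[keep], min(lab[c(i, j)]))
    dm <- dm2
  }
  b1 <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  b2 <- dm[1, 2] - b1
  b3 <- dm[1, 3] - b1
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(b1), sub[2], fmt(b2),
                    sub[3], fmt(b3))
  structure(list(newick = newick, tree = ape::read.tree(text = newick)),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("nj_tree with", length(x$tree$tip.label), "tips\n")
  invisible(x)
}
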