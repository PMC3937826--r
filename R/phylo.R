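#' Prune a phylogeny to the analyzed organisms
#'
#' Restricts the tree to the requested tips, collapsing degree-2 internal
#' nodes with branch lengths summed (so pairwise path lengths are
#' preserved) and keeping the root. Organisms missing from the tree are
#' reported in a warning and the analysis proceeds on the intersection.
#'
#' @param tree A rooted ape \code{phylo} with branch lengths.
#' @param organisms Character vector of tip labels to retain.
#' @return The pruned \code{phylo}.
#' @export
prune_to <- function(tree, organisms) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(organisms, tree$tip.label)
  if (length(missing)) {
    warning(sprintf("%d requested organism(s) absent from tree: %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  keep <- intersect(organisms, tree$tip.label)
  if (length(keep) < 2) {
    abort_oxymet("fewer than 2 requested tips present on the tree",
                 "oxymet_validation_error")
  }
  ape::keep.tip(tree, keep)
}

## Recursive node representation used for deterministic polytomy resolution.
phylo_to_rlist <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  build <- function(node, elen) {
    kid_edges <- children[[as.character(node)]]
    if (is.null(kid_edges)) {
      return(list(label = tree$tip.label[node], length = elen,
                  children = NULL))
    }
    kids <- lapply(kid_edges, function(e)
      build(tree$edge[e, 2], tree$edge.length[e]))
    list(label = NULL, length = elen, children = kids)
  }
  build(ntip + 1L, NA_real_)
}

## Smallest tip label in a subtree: the deterministic sort key.
rlist_min_label <- function(node) {
  if (is.null(node$children)) return(node$label)
  min(vapply(node$children, rlist_min_label, ""))
}

rlist_to_newick <- function(node) {
  fmt <- function(n) {
    body <- if (is.null(n$children)) n$label
            else paste0("(", paste(vapply(n$children, fmt, ""),
                                   collapse = ","), ")")
    if (is.na(n$length)) body else sprintf("%s:%.12g", body, n$length)
  }
  paste0(fmt(node), ";")
}

#' Resolve polytomies into a deterministic binary ladder
#'
#' Every multifurcation is replaced by a ladder of binary nodes joined by
#' branches of length \code{epsilon}: children are sorted by the smallest
#' tip label in their subtree, the first two are joined, then each next
#' child is added in turn. The tip set is unchanged and pairwise path
#' lengths are preserved up to (order of polytomy) x epsilon. Needed
#' because published trees of life contain multifurcations while the
#' contrast algorithm requires a binary tree.
#'
#' @param tree A rooted ape \code{phylo}.
#' @param epsilon Ladder branch length; minimum 1e-8 enforced.
#' @return A binary \code{phylo}.
#' @export
resolve_polytomies <- function(tree, epsilon = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(epsilon) || epsilon < 1e-8) {
    abort_oxymet("epsilon must be >= 1e-8", "oxymet_validation_error")
  }
  ## a basal multifurcation makes ape call the tree unrooted; treat it as
  ## a root polytomy to resolve
  if (ape::is.rooted(tree) && ape::is.binary(tree)) return(tree)
  resolve <- function(node) {
    if (is.null(node$children)) return(node)
    kids <- lapply(node$children, resolve)
    kids <- kids[order(vapply(kids, rlist_min_label, ""))]
    while (length(kids) > 2) {
      joined <- list(label = NULL, length = epsilon,
                     children = kids[1:2])
      kids <- c(list(joined), kids[-(1:2)])
    }
    node$children <- kids
    node
  }
  out <- ape::read.tree(text = rlist_to_newick(resolve(phylo_to_rlist(tree))))
  out
}

#' Phylogenetically independent contrasts for a binary predictor (brunch)
#'
#' Implements the CAIC-family brunch algorithm used to test whether a
#' continuous response (here, a network increase rate) is associated with
#' a binary trait (here, oxygen requirement) while controlling for shared
#' ancestry. A post-order traversal assigns each node branch-length
#' weighted averages of its daughters' predictor and response values
#' (weights proportional to 1 / adjusted branch length; a daughter's
#' branch is lengthened by v1*v2/(v1+v2) after an internal averaging, the
#' Felsenstein pruning rule). At every node whose two daughters differ in
#' (possibly fractional) predictor value the standardized response
#' contrast (value_high - value_low) / sqrt(v1' + v2') is emitted, signed
#' so the daughter with the larger predictor value is the minuend, and the
#' whole clade below the node is excluded from any further contrast — each
#' tip is used at most once, which is what makes the contrasts
#' independent. The association test is a one-sample t test of the k
#' contrasts against zero (df = k - 1), equivalent to a through-origin
#' regression on unit predictor contrasts; p is two-tailed.
#'
#' @param tree Rooted ape \code{phylo} with branch lengths; polytomies are
#'   resolved with [resolve_polytomies()] and zero-length branches raised
#'   to \code{epsilon} (counts reported).
#' @param predictor Named vector (by tip label) with values 0/1; both
#'   states must be present.
#' @param response Named numeric vector (by tip label).
#' @param tol Two daughter values are "different" when they differ by more
#'   than this; fractional nodal values arise below mixed-state clades.
#' @param epsilon Branch-length floor and polytomy ladder length.
#' @return A list of class \code{oxymet_contrasts}: data frame
#'   \code{contrasts} (node, contrast), \code{k}, \code{estimate} (mean
#'   contrast), \code{se}, \code{t_value}, \code{p_value} (NA with a
#'   warning when k < 2).
#' @export
brunch_contrasts <- function(tree, predictor, response,
                             tol = 1e-10, epsilon = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(predictor)) || !all(tips %in% names(response))) {
    abort_oxymet("every tip needs both predictor and response values",
                 "oxymet_validation_error")
  }
  pred_tip <- as.numeric(predictor[tips])
  resp_tip <- as.numeric(response[tips])
  if (!all(pred_tip %in% c(0, 1))) {
    abort_oxymet("predictor must be binary (0/1)", "oxymet_validation_error")
  }
  if (length(unique(pred_tip)) < 2) {
    abort_oxymet("predictor is constant across tips",
                 "oxymet_validation_error")
  }
  stopifnot(all(is.finite(resp_tip)))
  tree <- resolve_polytomies(tree, epsilon)
  n_zero <- sum(tree$edge.length < epsilon)
  if (n_zero > 0) {
    message(sprintf("raised %d short/zero branch length(s) to epsilon = %g",
                    n_zero, epsilon))
    tree$edge.length[tree$edge.length < epsilon] <- epsilon
  }

  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ## per-node state; elen = branch length to parent (NA at root)
  elen <- rep(NA_real_, nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  pred <- c(as.numeric(predictor[tree$tip.label]), rep(NA_real_, tree$Nnode))
  resp <- c(as.numeric(response[tree$tip.label]), rep(NA_real_, tree$Nnode))
  vadj <- ifelse(seq_len(nnode) <= ntip, elen, NA_real_)
  used <- rep(FALSE, nnode)

  out_node <- integer(0)
  out_contrast <- numeric(0)
  ## postorder edge matrix lists each internal node's edges consecutively
  parents <- unique(tree$edge[, 1])
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  for (n in parents) {
    kids <- kids_of[[as.character(n)]]
    stopifnot(length(kids) == 2L)
    avail <- !used[kids]
    if (!any(avail)) { used[n] <- TRUE; next }
    if (sum(avail) == 1L) {
      k <- kids[avail]
      pred[n] <- pred[k]; resp[n] <- resp[k]
      vadj[n] <- (if (is.na(elen[n])) 0 else elen[n]) + vadj[k]
      next
    }
    k1 <- kids[1]; k2 <- kids[2]
    v1 <- vadj[k1]; v2 <- vadj[k2]
    if (abs(pred[k1] - pred[k2]) > tol) {
      hi <- if (pred[k1] > pred[k2]) k1 else k2
      lo <- if (hi == k1) k2 else k1
      out_node <- c(out_node, n)
      out_contrast <- c(out_contrast, (resp[hi] - resp[lo]) / sqrt(v1 + v2))
      used[n] <- TRUE
    } else {
      w1 <- 1 / v1; w2 <- 1 / v2
      pred[n] <- (w1 * pred[k1] + w2 * pred[k2]) / (w1 + w2)
      resp[n] <- (w1 * resp[k1] + w2 * resp[k2]) / (w1 + w2)
      vadj[n] <- (if (is.na(elen[n])) 0 else elen[n]) + v1 * v2 / (v1 + v2)
    }
  }

  k <- length(out_contrast)
  est <- if (k > 0) mean(out_contrast) else NA_real_
  if (k >= 2) {
    se <- sd(out_contrast) / sqrt(k)
    t_value <- est / se
    p_value <- 2 * pt(-abs(t_value), df = k - 1)
  } else {
    warning("fewer than 2 contrasts; no test performed", call. = FALSE)
    se <- t_value <- p_value <- NA_real_
  }
  structure(list(
    contrasts = data.frame(node = out_node, contrast = out_contrast),
    k = k, estimate = est, se = se, t_value = t_value, p_value = p_value),
    class = "oxymet_contrasts")
}

#' @export
print.oxymet_contrasts <- function(x, ...) {
  cat(sprintf("Brunch contrasts: k = %d, estimate = %.5g +/- %.5g\n",
              x$k, x$estimate, x$se))
  if (is.finite(x$t_value %||% NA)) {
    cat(sprintf("  t = %.4g on %d df, two-tailed p = %.4g\n",
                x$t_value, x$k - 1, x$p_value))
  }
  invisible(x)
}
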