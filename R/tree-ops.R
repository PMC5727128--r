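#' Read a set of phylogenetic trees
#'
#' Reads one or more rooted trees from a Newick or Nexus file and validates
#' each one (unique tip labels, non-negative branch lengths, no singleton
#' internal nodes). Tree order in the file is preserved.
#'
#' @param source Path to a tree file.
#' @param format `"auto"` (default; Nexus is detected from the `#NEXUS`
#'   header), `"newick"` or `"nexus"`.
#' @return An object of class `multiPhylo` (a list of `phylo` trees), even
#'   for a single tree.
#' @seealso [write_tree_set()], [majority_consensus()]
#' @export
read_tree_set <- function(source, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(source)) {
    stop("tree file not found: ", source, call. = FALSE)
  }
  if (format == "auto") {
    first <- toupper(trimws(readLines(source, n = 1L, warn = FALSE)))
    format <- if (length(first) && startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(source) else ape::read.tree(source),
    error = function(e) {
      stop("failed to parse ", format, " file '", source, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(trees)) {
    stop("failed to parse ", format, " file '", source, "': no trees found",
         call. = FALSE)
  }
  trees <- as_tree_set(trees)
  for (i in seq_along(trees)) {
    validate_phylo(trees[[i]], context = paste0("tree ", i, " in '", source, "'"))
  }
  trees
}

#' Write a set of trees
#'
#' @param trees A `phylo`, `multiPhylo` or list of `phylo` objects.
#' @param path Output file path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree_set <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- as_tree_set(trees)
  if (format == "nexus") {
    ape::write.nexus(trees, file = path)
  } else {
    ape::write.tree(trees, file = path, digits = 15)
  }
  invisible(path)
}

## Coerce phylo / list / multiPhylo to multiPhylo.
as_tree_set <- function(trees) {
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
  }
  if (inherits(trees, "multiPhylo") && !is.null(attr(trees, "TipLabel"))) {
    # expand compressed tip labels so plain list iteration is safe
    trees <- lapply(seq_along(trees), function(i) trees[[i]])
  }
  if (!inherits(trees, "multiPhylo")) {
    if (!is.list(trees) || !all(vapply(trees, inherits, logical(1), "phylo"))) {
      stop("expected a 'phylo', 'multiPhylo' or list of 'phylo' objects",
           call. = FALSE)
    }
    class(trees) <- "multiPhylo"
  }
  trees
}

## Structural validity: unique tips, >=2 children per internal node,
## non-negative finite branch lengths.
validate_phylo <- function(tree, context = "tree") {
  if (!inherits(tree, "phylo")) stop(context, ": not a 'phylo' object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop(context, ": duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  kids <- tabulate(tree$edge[, 1], nbins = ape::Ntip(tree) + tree$Nnode)
  internal <- seq.int(ape::Ntip(tree) + 1L, ape::Ntip(tree) + tree$Nnode)
  if (any(kids[internal] < 2L)) {
    stop(context, ": internal node with fewer than 2 children", call. = FALSE)
  }
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
      stop(context, ": branch lengths must be finite and non-negative",
           call. = FALSE)
    }
  }
  invisible(tree)
}

#' Majority-rule consensus tree
#'
#' Builds the consensus containing exactly the non-trivial clades whose
#' frequency across the input trees strictly exceeds `threshold`. Each
#' consensus branch length is the arithmetic mean of that clade's subtending
#' edge length over the trees containing the clade; tip branch lengths are
#' averaged over all trees. All input trees must share one tip set.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) of rooted trees.
#' @param threshold Clade-frequency threshold, strict (default 0.5, i.e.
#'   classic ">50%" majority rule; clades at exactly the threshold are
#'   excluded).
#' @return A rooted `phylo` consensus tree with branch lengths.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  trees <- as_tree_set(trees)
  if (!length(trees)) stop("need at least one tree", call. = FALSE)
  if (threshold < 0.5 || threshold >= 1) {
    stop("threshold must be in [0.5, 1)", call. = FALSE)
  }
  tips0 <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    ti <- sort(trees[[i]]$tip.label)
    if (!identical(ti, tips0)) {
      d <- c(setdiff(ti, tips0), setdiff(tips0, ti))
      stop("tree ", i, " has a different tip set; symmetric difference: ",
           paste(d, collapse = ", "), call. = FALSE)
    }
  }

  n_tree <- length(trees)
  clade_count <- new.env(parent = emptyenv())
  clade_len <- new.env(parent = emptyenv())
  tip_len <- stats::setNames(numeric(length(tips0)), tips0)

  for (tr in trees) {
    ntip <- ape::Ntip(tr)
    root <- ntip + 1L
    has_len <- !is.null(tr$edge.length)
    parent_edge <- integer(ntip + tr$Nnode)
    parent_edge[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
    if (has_len) {
      tip_len[tr$tip.label] <- tip_len[tr$tip.label] +
        tr$edge.length[parent_edge[seq_len(ntip)]] / n_tree
    }
    if (tr$Nnode > 1L) {
      desc <- phangorn::Descendants(tr, seq.int(ntip + 2L, ntip + tr$Nnode), "tips")
      for (j in seq_along(desc)) {
        nd <- ntip + 1L + j
        key <- paste(sort(tr$tip.label[desc[[j]]]), collapse = "\r")
        clade_count[[key]] <- (clade_count[[key]] %||% 0L) + 1L
        if (has_len) {
          clade_len[[key]] <- (clade_len[[key]] %||% 0) +
            tr$edge.length[parent_edge[nd]]
        }
      }
    }
  }

  keys <- ls(clade_count)
  freq <- vapply(keys, function(k) clade_count[[k]], integer(1))
  keep <- keys[freq / n_tree > threshold]
  clades <- lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  mean_len <- vapply(keep, function(k) clade_len[[k]] / clade_count[[k]], numeric(1))

  fmt <- function(x) sprintf("%.15g", x)
  nest <- function(tipset, idx) {
    inside <- idx[order(-lengths(clades[idx]))]
    used <- character(0)
    parts <- character(0)
    for (i in inside) {
      cl <- clades[[i]]
      if (!any(cl %in% used)) {
        sub <- inside[vapply(inside, function(j) {
          j != i && all(clades[[j]] %in% cl)
        }, logical(1))]
        parts <- c(parts, paste0(nest(cl, sub), ":", fmt(mean_len[i])))
        used <- c(used, cl)
      }
    }
    loose <- setdiff(tipset, used)
    if (length(loose)) {
      parts <- c(parts, paste0(loose, ":", vapply(tip_len[loose], fmt,
                                                  character(1))))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }

  in_root <- which(lengths(clades) < length(tips0))
  nwk <- paste0(nest(tips0, in_root), ";")
  cons <- ape::read.tree(text = nwk)
  validate_phylo(cons, "consensus")
  cons
}

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' The entry for species i, j is the shared root-to-MRCA path length; under
#' the lambda transformation every off-diagonal entry is multiplied by
#' `lambda` while the diagonal (each tip's root-to-tip depth) is left
#' unchanged. `lambda = 1` gives the plain Brownian-motion covariance,
#' `lambda = 0` a diagonal matrix (no phylogenetic signal).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param lambda Signal multiplier in `[0, 1]`.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree, lambda = 1) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  V <- ape::vcv.phylo(tree)
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
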