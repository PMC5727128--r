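## Flat-file interfaces: species-by-trait tables as CSV/TSV, fit tables as
## TSV, and the end-to-end check against externally supplied published
## data (trait supplement plus downloaded tree set).

#' Read a species-by-trait table
#'
#' Expects a header row and one species column; the separator is taken
#' from the file extension (`.csv` vs `.tsv`/`.txt`) unless given.
#'
#' @param path File path.
#' @param sep Field separator; default inferred from the extension.
#' @param species_col Species column name (default `"species"`).
#' @return A data frame with the species column as character.
#' @export
read_trait_table <- function(path, sep = NULL, species_col = "species") {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!species_col %in% names(d)) {
    stop("no '", species_col, "' column in ", path, call. = FALSE)
  }
  d[[species_col]] <- trimws(as.character(d[[species_col]]))
  d
}

#' Write a species-by-trait table
#'
#' @param traits Data frame.
#' @param path Output path; `.csv` writes comma-separated, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(traits, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Recompute published-style allometric fits from external files
#'
#' Runs the full comparative pipeline on user-supplied data: reads a tree
#' set, builds the majority-rule consensus, and fits the requested PGLS
#' pairs on the supplied trait table. Intended for checking reported
#' slope/intercept/lambda/r-squared tables against their source data,
#' which ship separately (a measurement supplement and trees obtained from
#' a phylogeny service) and are not bundled here.
#'
#' @param traits_path Path to the species-by-trait CSV/TSV.
#' @param trees_path Path to the Newick/Nexus tree set.
#' @param pairs Pair table for [allometry_table()]; defaults to the
#'   olfactory-bulb scaling comparisons (OB against telencephalon-minus-OB
#'   and brain-minus-OB, mitral cells against OB, telencephalon and
#'   brain), used when the corresponding columns are present.
#' @param species_col Species column name.
#' @param match Species matching mode, `"error"` or `"intersect"` (see
#'   [fit_pgls()]); defaults to `"intersect"` since external trait tables
#'   and tree sets routinely differ in coverage.
#' @return The [allometry_table()] result, with the consensus tree
#'   attached as attribute `"consensus"`.
#' @export
published_fit_check <- function(traits_path, trees_path, pairs = NULL,
                                species_col = "species",
                                match = c("intersect", "error")) {
  match <- match.arg(match)
  traits <- read_trait_table(traits_path, species_col = species_col)
  trees <- read_tree_set(trees_path)
  cons <- majority_consensus(trees)
  if (is.null(pairs)) {
    pairs <- data.frame(
      response = c("olfactory_bulb", "olfactory_bulb", "mitral_cells",
                   "mitral_cells", "mitral_cells"),
      predictor = c("telencephalon", "brain", "olfactory_bulb",
                    "telencephalon", "brain"),
      subtract_response = c(TRUE, TRUE, FALSE, FALSE, FALSE)
    )
    have <- vapply(seq_len(nrow(pairs)), function(i) {
      all(c(pairs$response[i], pairs$predictor[i]) %in% names(traits))
    }, logical(1))
    pairs <- pairs[have, , drop = FALSE]
    if (!nrow(pairs)) {
      stop("no default trait pairs found in the table; pass 'pairs'",
           call. = FALSE)
    }
  }
  if (match == "intersect") {
    keep <- intersect(cons$tip.label, traits[[species_col]])
    cons <- ape::keep.tip(cons, keep)
    traits <- traits[traits[[species_col]] %in% keep, , drop = FALSE]
  }
  out <- allometry_table(cons, traits, pairs, species_col = species_col)
  attr(out, "consensus") <- cons
  out
}
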