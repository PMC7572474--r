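#' Rank-wise consensus taxonomy from marker-gene assignments
#'
#' Per rMAG and rank, each candidate taxon's score is the sum of the
#' assignment probabilities of the marker genes voting for it. The taxon
#' with the highest score wins; its confidence is its score over the total
#' score at that rank. When the winner holds less than `min_frac` (default
#' one third) of the total score, the call is discarded as
#' `"low confidence assignment"`. Ties are broken lexicographically with a
#' warning.
#'
#' @param assignments data.frame with taxon and probability columns (the
#'   marker assignments of one rMAG at one rank).
#' @param min_frac minimum winning fraction (default 1/3).
#' @return list with `taxon`, `confidence`, `low_confidence` (logical).
#' @export
consensus_assign <- function(assignments, min_frac = 1 / 3) {
  if (!nrow(assignments)) stop("no assignments at this rank", call. = FALSE)
  score <- tapply(assignments$probability, assignments$taxon, sum)
  total <- sum(score)
  if (total <= 0)
    return(list(taxon = "low confidence assignment", confidence = 0,
                low_confidence = TRUE))
  top <- max(score)
  winners <- sort(names(score)[score == top])
  if (length(winners) > 1)
    warning("tie between ", paste(winners, collapse = ", "),
            "; broken lexicographically", call. = FALSE)
  conf <- unname(top / total)
  if (conf < min_frac)
    return(list(taxon = "low confidence assignment", confidence = conf,
                low_confidence = TRUE))
  list(taxon = winners[1], confidence = conf, low_confidence = FALSE)
}

#' Merge genome-level and marker-consensus taxonomies into a lineage
#'
#' Genome-level (whole-genome comparison) calls take precedence; consensus
#' calls fill only ranks the genome comparison left unassigned. Lineages
#' without a kingdom-level call after merging are flagged for removal.
#'
#' @param genome_calls named character vector of taxa by rank (may miss
#'   ranks or be `NA`).
#' @param consensus_calls named character vector of consensus taxa by rank
#'   (entries equal to `"low confidence assignment"` are treated as
#'   unassigned).
#' @param ranks rank order, kingdom first.
#' @return data.frame with rank, taxon, source (`genome`/`consensus`/`NA`)
#'   and attribute `"remove"` (logical, no kingdom call).
#' @export
merge_assignments <- function(genome_calls, consensus_calls,
                              ranks = c("kingdom", "phylum", "class",
                                        "order", "family", "genus")) {
  usable <- function(v, r) r %in% names(v) && !is.na(v[r]) &&
    nzchar(v[r]) && v[r] != "low confidence assignment"
  taxon <- character(length(ranks))
  source <- rep(NA_character_, length(ranks))
  for (i in seq_along(ranks)) {
    r <- ranks[i]
    if (usable(genome_calls, r)) {
      taxon[i] <- genome_calls[[r]]
      source[i] <- "genome"
    } else if (usable(consensus_calls, r)) {
      taxon[i] <- consensus_calls[[r]]
      source[i] <- "consensus"
    } else {
      taxon[i] <- NA_character_
    }
  }
  out <- data.frame(rank = ranks, taxon = taxon, source = source,
                    stringsAsFactors = FALSE)
  attr(out, "remove") <- is.na(taxon[1])
  out
}

#' Consensus lineages for a marker-assignment table
#'
#' Applies [consensus_assign()] per rMAG and rank and merges with
#' genome-level calls via [merge_assignments()].
#'
#' @param markers data.frame with rmag_id, marker_id, rank, taxon,
#'   probability.
#' @param genome_tax optional data.frame with rmag_id, rank, taxon.
#' @param ranks rank order, kingdom first.
#' @return data.frame with rmag_id, rank, taxon, source, confidence and a
#'   `remove` flag per rMAG (no kingdom-level call).
#' @export
consensus_lineages <- function(markers, genome_tax = NULL,
                               ranks = c("kingdom", "phylum", "class",
                                         "order", "family", "genus")) {
  out <- list()
  for (r_id in unique(markers$rmag_id)) {
    mk <- markers[markers$rmag_id == r_id, ]
    cons <- vapply(ranks, function(rk) {
      at <- mk[mk$rank == rk, ]
      if (!nrow(at)) return(NA_character_)
      consensus_assign(at)$taxon
    }, character(1))
    conf <- vapply(ranks, function(rk) {
      at <- mk[mk$rank == rk, ]
      if (!nrow(at)) return(NA_real_)
      consensus_assign(at)$confidence
    }, numeric(1))
    gen <- if (!is.null(genome_tax)) {
      gt <- genome_tax[genome_tax$rmag_id == r_id, ]
      stats::setNames(gt$taxon, gt$rank)
    } else stats::setNames(character(0), character(0))
    lineage <- merge_assignments(gen, cons, ranks)
    lineage$rmag_id <- r_id
    lineage$confidence <- ifelse(lineage$source %in% "consensus",
                                 conf[lineage$rank], NA_real_)
    lineage$remove <- attr(lineage, "remove")
    out[[r_id]] <- lineage
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("rmag_id", "rank", "taxon", "source", "confidence", "remove")]
}
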