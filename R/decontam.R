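#' Summarize taxonomic hits per scaffold
#'
#' Aggregates per-hit taxonomic assignments within each scaffold into a
#' metazoan fraction.  Hits may carry either a logical `is_metazoan` column
#' or a `lineage` string; a lineage counts as metazoan when its path
#' contains the metazoan clade label (case-insensitive), and unresolved or
#' unclassified lineages count as non-metazoan.
#'
#' @param hits data.frame with columns `scaffold_id`, `hit_id`, and either
#'   `is_metazoan` (logical) or `lineage` (character).
#' @param metazoan_label clade label looked up in `lineage` paths.
#' @param strict if `TRUE`, malformed rows (empty scaffold id, missing
#'   taxonomy) are fatal; otherwise they are skipped with a warning naming
#'   the row numbers.
#' @return data.frame with one row per scaffold: `scaffold_id`, `n_hits`,
#'   `metazoan_fraction`.
#' @export
summarize_scaffold_taxonomy <- function(hits, metazoan_label = "Metazoa",
                                        strict = FALSE) {
  if (!"scaffold_id" %in% names(hits))
    stop("hits must have a scaffold_id column")
  if ("is_metazoan" %in% names(hits)) {
    met <- as.logical(hits$is_metazoan)
  } else if ("lineage" %in% names(hits)) {
    met <- grepl(metazoan_label, hits$lineage, ignore.case = TRUE)
    met[is.na(hits$lineage) | hits$lineage == ""] <- FALSE
  } else {
    stop("hits must have an is_metazoan or lineage column")
  }
  bad <- is.na(hits$scaffold_id) | hits$scaffold_id == "" | is.na(met)
  if (any(bad)) {
    msg <- paste0("malformed hit rows at lines: ",
                  paste(utils::head(which(bad), 20), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; skipped")
    hits <- hits[!bad, , drop = FALSE]
    met <- met[!bad]
  }
  if (!nrow(hits))
    return(data.frame(scaffold_id = character(0), n_hits = integer(0),
                      metazoan_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  n <- tapply(met, hits$scaffold_id, length)
  m <- tapply(met, hits$scaffold_id, sum)
  out <- data.frame(scaffold_id = names(n), n_hits = as.integer(n),
                    metazoan_fraction = as.numeric(m) / as.numeric(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$scaffold_id), , drop = FALSE]
}

#' Flag contaminant scaffolds by taxonomic majority vote
#'
#' A scaffold is removed when it has at least one taxonomic hit and strictly
#' less than `min_metazoan` of its hits are metazoan.  Scaffolds without
#' hits are kept: absence of evidence is not treated as contamination.
#'
#' @param summaries output of [summarize_scaffold_taxonomy()].
#' @param all_scaffolds character vector of every scaffold in the assembly,
#'   in assembly order.
#' @param min_metazoan removal threshold on the metazoan fraction
#'   (default 0.90; a fraction exactly at the threshold is kept).
#' @return list with `keep` and `remove` character vectors partitioning
#'   `all_scaffolds` (each in assembly order).
#' @export
flag_contaminant_scaffolds <- function(summaries, all_scaffolds,
                                       min_metazoan = 0.90) {
  if (min_metazoan < 0 || min_metazoan > 1)
    stop("min_metazoan must be in [0, 1]")
  unknown <- setdiff(summaries$scaffold_id, all_scaffolds)
  if (length(unknown))
    stop("summaries reference scaffolds absent from the assembly: ",
         paste(utils::head(unknown), collapse = ", "))
  bad <- summaries$scaffold_id[summaries$n_hits > 0 &
                                 summaries$metazoan_fraction < min_metazoan]
  remove <- all_scaffolds[all_scaffolds %in% bad]
  keep <- all_scaffolds[!all_scaffolds %in% bad]
  list(keep = keep, remove = remove)
}

#' Renumber surviving pseudochromosomes consecutively
#'
#' After contaminant removal, surviving scaffolds whose names carry a
#' trailing number are renumbered consecutively (1, 2, ...) in their
#' original assembly order, keeping any name prefix; scaffolds without a
#' numeric component pass through unchanged.
#'
#' @param kept character vector of surviving scaffold names, in assembly
#'   order.
#' @param removed character vector of removed scaffold names.
#' @return named character vector mapping old names to new names for every
#'   kept scaffold (an injective map).
#' @export
renumber_scaffolds <- function(kept, removed = character(0)) {
  if (length(intersect(kept, removed)))
    stop("kept and removed overlap")
  m <- regmatches(kept, regexec("^(.*?)([0-9]+)$", kept))
  has_num <- lengths(m) == 3
  new <- kept
  if (any(has_num)) {
    prefix <- vapply(m[has_num], `[`, character(1), 2)
    if (length(unique(prefix)) > 1) {
      # renumber within each prefix group independently
      for (p in unique(prefix)) {
        sel <- has_num & vapply(m, function(x)
          length(x) == 3 && x[2] == p, logical(1))
        new[sel] <- paste0(p, seq_len(sum(sel)))
      }
    } else {
      new[has_num] <- paste0(prefix, seq_len(sum(has_num)))
    }
  }
  if (anyDuplicated(new))
    stop("renumbering produced duplicate names: ",
         paste(unique(new[duplicated(new)]), collapse = ", "))
  stats::setNames(new, kept)
}

#' Classify reads by repeat-masked fraction
#'
#' Reads are `high` when more than 50% of the read length is repeat-masked,
#' `mild` when more than 25% (but at most 50%), and `low` otherwise.  Both
#' boundaries are strict: a fraction of exactly 0.25 is `low` and exactly
#' 0.50 is `mild`.
#'
#' @param profiles data.frame with a `repeat_fraction` column in \[0, 1\]
#'   (e.g. from [emit_read_repeat_profiles()]).
#' @param high_cutoff,mild_cutoff class boundaries (defaults 0.50 / 0.25).
#' @return list with `counts` (named integer vector over high/mild/low) and
#'   `class` (per-read factor).
#' @export
classify_repeat_reads <- function(profiles, high_cutoff = 0.50,
                                  mild_cutoff = 0.25) {
  fr <- profiles$repeat_fraction
  if (is.null(fr)) stop("profiles must have a repeat_fraction column")
  if (any(is.na(fr) | fr < 0 | fr > 1))
    stop("repeat_fraction outside [0, 1]")
  cls <- ifelse(fr > high_cutoff, "high",
                ifelse(fr > mild_cutoff, "mild", "low"))
  cls <- factor(cls, levels = c("high", "mild", "low"))
  counts <- stats::setNames(as.integer(table(cls)), levels(cls))
  stopifnot(sum(counts) == length(fr))
  list(counts = counts, class = cls)
}
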