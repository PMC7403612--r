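# Category-level summaries and cross-species ortholog-group counting.

#' The 16 functional categories
#'
#' Fixed vocabulary of custom-defined functional categories, roughly
#' following the KEGG pathway classification as applied to organellar
#' proteomes; a custom vocabulary can be supplied via a plain-text file
#' (one category per line). `"unknown"` is always allowed in addition.
#'
#' @param file Optional path to a custom vocabulary file.
#' @return Character vector of category names.
#' @export
category_vocabulary <- function(file = NULL) {
  if (!is.null(file)) {
    v <- trimws(readLines(file, warn = FALSE))
    v <- v[nzchar(v)]
    if (length(v) == 0) stop("empty category vocabulary file", call. = FALSE)
    return(v)
  }
  c(
    "core metabolic pathways",
    "ribosome, aminoacyl-tRNA biosynthesis and translation",
    "protein transport, folding, processing and degradation",
    "oxidative phosphorylation and electron transport",
    "RNA processing and degradation",
    "DNA replication, repair and nucleotide metabolism",
    "transcription and its regulation",
    "amino acid metabolism",
    "fatty acid and lipid metabolism",
    "carbohydrate metabolism",
    "Fe-S cluster biosynthesis",
    "sulfur metabolism",
    "transporters and carriers",
    "signaling and regulation",
    "redox homeostasis and stress response",
    "vitamin and cofactor metabolism"
  )
}

#' Per-category summary of the final proteome
#'
#' Counts members per functional category and summarises each category's
#' Mt/Cp enrichment by the geometric mean of its finite ratios (ratios
#' are multiplicative, so the geometric mean is the natural center);
#' members with infinite ratios are tallied separately and excluded from
#' the mean. The category log10 bin is `infinite` when only infinite
#' ratios exist, else `0-1` (1-10x), `1-2` (10-100x) or `>2`. The
#' unknown-function fraction is reported as a count and an integer
#' percent (round half away from zero).
#'
#' @param members Tibble with columns `id`, `category`, `ratio_mt_cp`.
#' @param vocabulary Closed category vocabulary (default
#'   [category_vocabulary()]); a category outside it (other than
#'   `"unknown"`) is an input error.
#' @return List: `categories` (tibble: `category`, `n`, `geomean_ratio`,
#'   `n_infinite`, `log10_bin`), `n_total`, `n_unknown`,
#'   `unknown_percent`, `n_annotated`.
#' @export
category_summary <- function(members, vocabulary = category_vocabulary()) {
  bad <- setdiff(unique(members$category), c(vocabulary, "unknown"))
  if (length(bad) > 0) {
    stop(
      "unknown category label(s): ", paste(bad, collapse = "; "),
      call. = FALSE
    )
  }
  per_cat <- lapply(vocabulary, function(cat) {
    rows <- members[members$category == cat, , drop = FALSE]
    r <- rows$ratio_mt_cp
    finite <- r[is.finite(r) & !is.nan(r) & r > 0]
    n_inf <- sum(is.infinite(r))
    gm <- if (length(finite) > 0) exp(mean(log(finite))) else NA_real_
    lg <- if (!is.na(gm)) log10(gm) else NA_real_
    bin <- if (nrow(rows) == 0) {
      NA_character_
    } else if (is.na(gm)) {
      if (n_inf > 0) "infinite" else NA_character_
    } else if (lg > 2) {
      ">2"
    } else if (lg > 1) {
      "1-2"
    } else if (lg > 0) {
      "0-1"
    } else {
      "not_enriched"
    }
    tibble::tibble(
      category = cat, n = nrow(rows), geomean_ratio = gm,
      n_infinite = n_inf, log10_bin = bin
    )
  })
  categories <- dplyr::bind_rows(per_cat)
  n_total <- nrow(members)
  n_unknown <- sum(members$category == "unknown")
  list(
    categories = categories,
    n_total = n_total,
    n_unknown = n_unknown,
    unknown_percent = if (n_total > 0) percent_round(n_unknown, n_total) else NA_integer_,
    n_annotated = n_total - n_unknown
  )
}

#' Cross-species ortholog-group counts
#'
#' Counts the other-species transcripts that share an ortholog group
#' with at least one member of the focal proteome, the number of
#' distinct such groups (always at most the transcript count), and how
#' many of those transcripts are orthologous to functionally
#' uncategorized focal proteins.
#'
#' @param group_table Tibble: `group_id`, `species`, `gene`.
#' @param focal_ids Identifiers of the focal proteome members.
#' @param focal_species,other_species Species labels in `group_table`.
#' @param uncategorized_ids Optional identifiers of focal members with
#'   unknown function.
#' @return List: `transcripts`, `groups`, `uncategorized_transcripts`.
#' @export
cross_species_counts <- function(group_table, focal_ids,
                                 focal_species, other_species,
                                 uncategorized_ids = character()) {
  focal <- group_table[
    group_table$species == focal_species &
      group_table$gene %in% focal_ids, ,
    drop = FALSE
  ]
  shared_groups <- unique(focal$group_id)
  other <- group_table[
    group_table$species == other_species &
      group_table$group_id %in% shared_groups, ,
    drop = FALSE
  ]
  uncat_groups <- unique(focal$group_id[focal$gene %in% uncategorized_ids])
  list(
    transcripts = length(unique(other$gene)),
    groups = length(unique(other$group_id)),
    uncategorized_transcripts = length(unique(
      other$gene[other$group_id %in% uncat_groups]
    ))
  )
}
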