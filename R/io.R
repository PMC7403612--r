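# Readers and writers for the standard tabular formats the pipeline
# consumes and emits. All TSVs are UTF-8, tab-delimited with a header.

#' Write and read a generic TSV table
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv_table` returns a tibble; writers return the path
#'   invisibly.
#' @export
write_tsv_table <- function(x, path) {
  df <- as.data.frame(x)
  list_cols <- vapply(df, is.list, logical(1))
  for (col in names(df)[list_cols]) {
    df[[col]] <- vapply(
      df[[col]],
      function(v) paste(v, collapse = ";"), character(1)
    )
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a proteome to FASTA
#'
#' @param proteome Tibble with `protein_id` and `sequence`.
#' @param path Output path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  seqs <- Biostrings::AAStringSet(proteome$sequence)
  names(seqs) <- proteome$protein_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a protein FASTA
#'
#' @param path FASTA path.
#' @return Tibble: `protein_id`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = sub(" .*", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}

#' Write/read peptide observations (long TSV)
#'
#' Columns: `peptide`, `protein_ids`, `fraction`, `replicate`,
#' `intensity`.
#'
#' @param observations Observation tibble.
#' @param path File path.
#' @export
write_observations <- function(observations, path) {
  write_tsv_table(observations, path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- read_tsv_table(path)
  need <- c("peptide", "protein_ids", "fraction", "replicate", "intensity")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols) > 0) {
    stop(
      path, " lacks observation columns: ",
      paste(missing_cols, collapse = ", "), call. = FALSE
    )
  }
  out
}

#' Write a MaxQuant-flavoured peptides table
#'
#' Columns `Sequence`, `Proteins` and one `Intensity <sample>` column
#' per sample, re-readable by [read_peptides_table()].
#'
#' @param matches Tibble from [peptide_matches()].
#' @param path File path.
#' @export
write_peptides_table <- function(matches, path) {
  sample_cols <- setdiff(names(matches), c("peptide", "proteins"))
  df <- tibble::tibble(
    Sequence = matches$peptide,
    Proteins = vapply(matches$proteins, paste, character(1), collapse = ";")
  )
  for (s in sample_cols) df[[paste("Intensity", s)]] <- matches[[s]]
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a MaxQuant-flavoured peptides table
#'
#' @param path File path.
#' @return Tibble in [peptide_matches()] form.
#' @export
read_peptides_table <- function(path) {
  df <- read_tsv_table(path)
  if (!all(c("Sequence", "Proteins") %in% names(df))) {
    stop(path, " lacks Sequence/Proteins columns", call. = FALSE)
  }
  int_cols <- grep("^Intensity ", names(df), value = TRUE)
  out <- tibble::tibble(
    peptide = df$Sequence,
    proteins = lapply(strsplit(df$Proteins, ";", fixed = TRUE), sort)
  )
  for (s in int_cols) out[[sub("^Intensity ", "", s)]] <- df[[s]]
  out
}

#' Write a MaxQuant-flavoured proteinGroups table
#'
#' Columns `Protein IDs`, `Majority protein IDs`, `Unique peptides` and
#' one `LFQ intensity <sample>` column per sample.
#'
#' @param groups Tibble from [group_proteins()].
#' @param unique_counts `counts` tibble from [count_unique_peptides()].
#' @param intensities Tibble from [aggregate_group_intensity()].
#' @param path File path.
#' @export
write_protein_groups_table <- function(groups, unique_counts, intensities, path) {
  uc <- stats::setNames(unique_counts$unique_peptides, unique_counts$group_id)
  df <- tibble::tibble(
    `Protein IDs` = vapply(groups$members, paste, character(1), collapse = ";"),
    `Majority protein IDs` = groups$leader,
    `Unique peptides` = as.integer(uc[groups$group_id])
  )
  sample_cols <- setdiff(names(intensities), c("group_id", "quantifiable"))
  ints <- intensities[match(groups$group_id, intensities$group_id), ]
  for (s in sample_cols) df[[paste("LFQ intensity", s)]] <- ints[[s]]
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a TargetP-style localization table
#'
#' Expects tab-delimited columns `name`, `loc`, `RC`, `start_met`.
#'
#' @param path File path.
#' @return Tibble with those columns (`start_met` logical).
#' @export
read_targetp <- function(path) {
  df <- read_tsv_table(path)
  need <- c("name", "loc", "start_met")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(
      path, " lacks TargetP columns: ",
      paste(missing_cols, collapse = ", "), call. = FALSE
    )
  }
  df$start_met <- as.logical(df$start_met)
  df
}

#' Read a BLAST tabular (outfmt 6) file
#'
#' Standard 12 columns; only query, subject, e-value and bit score are
#' retained, tagged `tool = "blast"`.
#'
#' @param path File path.
#' @return Tibble: `query`, `target`, `e_value`, `bit_score`, `tool`.
#' @export
read_blast_tab <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c(
      "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
      "qstart", "qend", "sstart", "send", "evalue", "bitscore"
    ),
    show_col_types = FALSE, progress = FALSE
  )
  tibble::tibble(
    query = df$qseqid, target = df$sseqid,
    e_value = df$evalue, bit_score = df$bitscore, tool = "blast"
  )
}

#' Read a HMMER tblout-style file
#'
#' Whitespace-delimited `--tblout` layout: target name, target
#' accession, query name, query accession, then the full-sequence
#' E-value, score and bias. Comment lines start with `#`.
#'
#' @param path File path.
#' @return Tibble: `query`, `target`, `e_value`, `score`, `bias`,
#'   `tool`.
#' @export
read_hmmer_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(
      query = character(), target = character(), e_value = numeric(),
      score = numeric(), bias = numeric(), tool = character()
    ))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  short <- lengths(fields) < 7
  if (any(short)) {
    stop(path, " has tblout rows with fewer than 7 fields", call. = FALSE)
  }
  tibble::tibble(
    target = vapply(fields, `[`, character(1), 1),
    query = vapply(fields, `[`, character(1), 3),
    e_value = as.numeric(vapply(fields, `[`, character(1), 5)),
    score = as.numeric(vapply(fields, `[`, character(1), 6)),
    bias = as.numeric(vapply(fields, `[`, character(1), 7)),
    tool = "hmm"
  )
}

#' Read an orthogroups table (OrthoFinder-style)
#'
#' Tab-delimited with an `Orthogroup` column and one column per species
#' holding comma-separated gene lists.
#'
#' @param path File path.
#' @return Long tibble: `group_id`, `species`, `gene`.
#' @export
read_orthogroups <- function(path) {
  df <- read_tsv_table(path)
  if (!"Orthogroup" %in% names(df)) {
    stop(path, " lacks an Orthogroup column", call. = FALSE)
  }
  species <- setdiff(names(df), "Orthogroup")
  rows <- lapply(species, function(sp) {
    genes <- strsplit(ifelse(is.na(df[[sp]]), "", df[[sp]]), ",[ ]?")
    n <- lengths(genes)
    tibble::tibble(
      group_id = rep(df$Orthogroup, n),
      species = sp,
      gene = trimws(unlist(genes, use.names = FALSE))
    )
  })
  out <- dplyr::bind_rows(rows)
  out[nzchar(out$gene), , drop = FALSE]
}

#' Write a summary list as JSON
#'
#' @param summary Named list of scalars.
#' @param path File path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
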