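# Synthetic fractionation experiment: ground-truth proteomes and every
# downstream input table the pipeline consumes.

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic fractionation experiment
#'
#' Bundles every tunable of the generator: proteome composition, the true
#' mitochondrial-fraction fold enrichment, intensity noise, observation
#' missingness, transcriptome 5'-truncation, and reference-orthology
#' coverage. Defaults describe a photosynthetic protist whose organellar
#' bands cross-contaminate each other on a sucrose gradient while soluble
#' cytosolic proteins are washed out, whose transcripts frequently lose
#' the 5' targeting signal, and whose proteins are divergent enough that
#' any single reference mitoproteome covers only a minority of them.
#'
#' @param n_proteins Number of proteins in the ground-truth proteome.
#' @param localization_proportions Named numeric vector over
#'   `mito`, `chloroplast`, `cytosol`, `dual`; must sum to 1.
#' @param enrichment_fold True fold enrichment of a resident protein in
#'   its organellar fraction (dimensionless, > 0).
#' @param intensity_log_sd Standard deviation of multiplicative
#'   log10-normal intensity noise.
#' @param n_replicates_per_fraction Replicates per fraction.
#' @param missing_rate Probability an individual peptide observation
#'   (peptide x fraction x replicate) is absent.
#' @param detectability Probability a tryptic peptide is observable at all.
#' @param truncation_prob Probability a transcriptome variant's ORF is
#'   5'-truncated, losing both the targeting signal and the start
#'   methionine.
#' @param reference_coverage Probability a true mitochondrial protein has
#'   an ortholog in a given reference mitoproteome.
#' @param n_reference_proteomes Number of reference mitoproteomes.
#' @param seed Integer seed; all generators are deterministic given the
#'   config.
#' @param min_peptide_length Minimum tryptic peptide length retained.
#' @param missed_cleavages Missed cleavages allowed by the digest (0-2).
#' @param contaminant_rate Fraction of cytosolic proteins that co-sediment
#'   with the mitochondrial band (and carry a clear non-mitochondrial
#'   annotation).
#' @param leak_factor Median mito-band abundance of a contaminant
#'   relative to `enrichment_fold`; per-protein multipliers are
#'   lognormal around it (sd 0.5 log10 units), so a minority of
#'   contaminants co-sediment strongly enough to look enriched.
#' @param ortholog_fp_rate Per-reference probability a non-mitochondrial
#'   protein spuriously matches an ortholog group.
#' @param targeting_fp_rate Per-transcriptome probability a protein
#'   without a targeting signal is predicted mitochondrial anyway.
#' @param annotation_rate Probability a mitochondrial protein carries a
#'   curated mitochondrial functional annotation (and one of the 16
#'   functional categories).
#' @param predicted_mito_coverage Probability a true mitochondrial protein
#'   is in the in-silico predicted mitoproteome.
#' @param predicted_mito_fp_rate Same for non-mitochondrial proteins.
#' @param id_score_separation Mean separation (in score SD units) between
#'   target and decoy identification scores.
#' @param mean_sequence_length Mean protein length in residues.
#' @param base_abundance_log_mean,base_abundance_log_sd log10 mean and sd
#'   of per-protein base abundance.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 2000,
                              localization_proportions = c(
                                mito = 0.35, chloroplast = 0.25,
                                cytosol = 0.35, dual = 0.05
                              ),
                              enrichment_fold = 8,
                              intensity_log_sd = 0.2,
                              n_replicates_per_fraction = 3,
                              missing_rate = 0.1,
                              detectability = 0.5,
                              truncation_prob = 0.8,
                              reference_coverage = 0.2,
                              n_reference_proteomes = 4,
                              seed = 1L,
                              min_peptide_length = 6,
                              missed_cleavages = 0,
                              contaminant_rate = 0.05,
                              leak_factor = 0.1,
                              ortholog_fp_rate = 0.01,
                              targeting_fp_rate = 0.02,
                              annotation_rate = 0.45,
                              predicted_mito_coverage = 0.5,
                              predicted_mito_fp_rate = 0.02,
                              id_score_separation = 5,
                              mean_sequence_length = 350,
                              base_abundance_log_mean = 6,
                              base_abundance_log_sd = 0.8) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    localization_proportions = localization_proportions,
    enrichment_fold = enrichment_fold,
    intensity_log_sd = intensity_log_sd,
    n_replicates_per_fraction = as.integer(n_replicates_per_fraction),
    missing_rate = missing_rate,
    detectability = detectability,
    truncation_prob = truncation_prob,
    reference_coverage = reference_coverage,
    n_reference_proteomes = as.integer(n_reference_proteomes),
    seed = as.integer(seed),
    min_peptide_length = as.integer(min_peptide_length),
    missed_cleavages = as.integer(missed_cleavages),
    contaminant_rate = contaminant_rate,
    leak_factor = leak_factor,
    ortholog_fp_rate = ortholog_fp_rate,
    targeting_fp_rate = targeting_fp_rate,
    annotation_rate = annotation_rate,
    predicted_mito_coverage = predicted_mito_coverage,
    predicted_mito_fp_rate = predicted_mito_fp_rate,
    id_score_separation = id_score_separation,
    mean_sequence_length = mean_sequence_length,
    base_abundance_log_mean = base_abundance_log_mean,
    base_abundance_log_sd = base_abundance_log_sd
  )
  validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$localization_proportions
  expected <- c("mito", "chloroplast", "cytosol", "dual")
  if (!all(expected %in% names(p))) {
    stop("localization_proportions must be named over mito, chloroplast, cytosol, dual",
      call. = FALSE
    )
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("localization_proportions must sum to 1 (got ", sum(p), ")", call. = FALSE)
  }
  if (any(p < 0)) stop("localization_proportions must be nonnegative", call. = FALSE)
  probs <- c(
    cfg$missing_rate, cfg$detectability, cfg$truncation_prob,
    cfg$reference_coverage, cfg$contaminant_rate, cfg$ortholog_fp_rate,
    cfg$targeting_fp_rate, cfg$annotation_rate,
    cfg$predicted_mito_coverage, cfg$predicted_mito_fp_rate
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$enrichment_fold <= 0) stop("enrichment_fold must be > 0", call. = FALSE)
  if (cfg$intensity_log_sd < 0) stop("intensity_log_sd must be >= 0", call. = FALSE)
  if (cfg$n_proteins < 0) stop("n_proteins must be >= 0", call. = FALSE)
  if (!cfg$missed_cleavages %in% 0:2) stop("missed_cleavages must be 0, 1 or 2", call. = FALSE)
  invisible(cfg)
}

# Integer allocation matching proportions to within rounding
# (largest-remainder method; deterministic).
allocate_counts <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a ground-truth proteome
#'
#' Draws `n_proteins` random amino-acid sequences with a true subcellular
#' localization, targeting-signal status, contaminant annotation,
#' in-silico prediction status, and functional category. Deterministic
#' given the config (including its seed).
#'
#' @param config A [simulation_config()].
#' @return Tibble with one row per protein: `protein_id`, `sequence`,
#'   `localization`, `has_targeting_signal`, `is_contaminant_annotation`,
#'   `contaminant_leak`, `annotation_mito_function`, `predicted_mito`,
#'   `category`, `base_abundance`.
#' @export
generate_proteome <- function(config) {
  validate_config(config)
  n <- config$n_proteins
  locs <- c("mito", "chloroplast", "cytosol", "dual")
  if (n == 0) {
    return(tibble::tibble(
      protein_id = character(), sequence = character(),
      localization = character(), has_targeting_signal = logical(),
      is_contaminant_annotation = logical(), contaminant_leak = numeric(),
      annotation_mito_function = logical(), predicted_mito = logical(),
      category = character(), base_abundance = numeric()
    ))
  }
  with_seed(config$seed, {
    counts <- allocate_counts(n, config$localization_proportions[locs])
    localization <- sample(rep(locs, counts))
    lens <- pmax(
      50L,
      as.integer(round(stats::rlnorm(n,
        meanlog = log(config$mean_sequence_length), sdlog = 0.4
      )))
    )
    sequence <- vapply(
      lens,
      function(L) paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
      character(1)
    )
    is_mito <- localization %in% c("mito", "dual")
    has_signal <- is_mito
    contaminant <- localization == "cytosol" &
      stats::runif(n) < config$contaminant_rate
    # Contaminants co-sediment with the mitochondrial band to very
    # different degrees (vesicles vs loosely attached material): their
    # mito-band abundance is enrichment_fold x a lognormal multiplier
    # centred on leak_factor, so a minority look genuinely enriched and
    # must be caught by annotation-based curation.
    leak <- ifelse(
      contaminant,
      10^stats::rnorm(n, log10(config$leak_factor), 0.5),
      0
    )
    annotated_mito <- is_mito & stats::runif(n) < config$annotation_rate
    predicted <- ifelse(
      is_mito,
      stats::runif(n) < config$predicted_mito_coverage,
      stats::runif(n) < config$predicted_mito_fp_rate
    )
    vocab <- category_vocabulary()
    category <- rep("unknown", n)
    category[annotated_mito] <- sample(vocab, sum(annotated_mito), replace = TRUE)
    base <- 10^stats::rnorm(
      n, config$base_abundance_log_mean, config$base_abundance_log_sd
    )
    tibble::tibble(
      protein_id = sprintf("EG%05d", seq_len(n)),
      sequence = sequence,
      localization = localization,
      has_targeting_signal = has_signal,
      is_contaminant_annotation = contaminant,
      contaminant_leak = leak,
      annotation_mito_function = annotated_mito,
      predicted_mito = predicted,
      category = category,
      base_abundance = base
    )
  })
}

#' Tryptic in-silico digest
#'
#' Cleaves C-terminal to K or R except when the next residue is P, keeps
#' peptides of at least `min_length` residues, and optionally joins up to
#' `missed_cleavages` adjacent fragments. With no length filter and no
#' missed cleavages, concatenating the returned peptides restores the
#' input sequence.
#'
#' @param sequence Single amino-acid string.
#' @param min_length Minimum peptide length retained (default 6).
#' @param missed_cleavages Number of missed cleavages allowed (0-2).
#' @return Character vector of peptides in N-to-C order (fully cleaved
#'   peptides first, then +1, +2 missed-cleavage products).
#' @examples
#' digest_tryptic("AAAAAKCCCDDD", min_length = 6)
#' @export
digest_tryptic <- function(sequence, min_length = 6, missed_cleavages = 0) {
  stopifnot(length(sequence) == 1, is.character(sequence))
  assert_aa(sequence)
  if (!missed_cleavages %in% 0:2) {
    stop("missed_cleavages must be 0, 1 or 2", call. = FALSE)
  }
  if (nchar(sequence) == 0) {
    return(character())
  }
  frags <- strsplit(
    gsub("(?<=[KR])(?!P)", "\x01", sequence, perl = TRUE), "\x01"
  )[[1]]
  peptides <- frags
  if (missed_cleavages > 0 && length(frags) > 1) {
    for (mc in seq_len(missed_cleavages)) {
      if (length(frags) <= mc) break
      idx <- seq_len(length(frags) - mc)
      joined <- vapply(
        idx,
        function(i) paste(frags[i:(i + mc)], collapse = ""),
        character(1)
      )
      peptides <- c(peptides, joined)
    }
  }
  peptides[nchar(peptides) >= min_length]
}

# Vectorised fully-cleaved digest over many sequences; returns a
# two-column tibble (protein_id, peptide) with the length filter applied.
digest_proteome <- function(proteome, min_length = 6) {
  frag_list <- strsplit(
    gsub("(?<=[KR])(?!P)", "\x01", proteome$sequence, perl = TRUE), "\x01"
  )
  n_per <- lengths(frag_list)
  out <- tibble::tibble(
    protein_id = rep(proteome$protein_id, n_per),
    peptide = unlist(frag_list, use.names = FALSE)
  )
  out[nchar(out$peptide) >= min_length, ]
}

# Relative abundance of each protein in the three fractions.
# Organellar bands cross-contaminate each other at base level; soluble
# cytosolic proteins are washed out of both organellar bands unless they
# co-sediment as contaminants; the whole cell contains everything.
fraction_effects <- function(truth, config) {
  fold <- config$enrichment_fold
  loc <- truth$localization
  leak <- truth$contaminant_leak %||% rep(0, nrow(truth))
  mt <- ifelse(loc %in% c("mito", "dual"), fold,
    ifelse(loc == "chloroplast", 1,
      ifelse(truth$is_contaminant_annotation, leak * fold, 0)
    )
  )
  cp <- ifelse(loc %in% c("chloroplast", "dual"), fold,
    ifelse(loc == "mito", 1, 0)
  )
  tibble::tibble(protein_id = truth$protein_id, mt = mt, cp = cp, wc = 1)
}

#' Simulate peptide-level fraction observations
#'
#' Digests every protein, decides which peptides are observable at all,
#' then emits one intensity per surviving (peptide, fraction, replicate):
#' `base_abundance x fraction_effect x 10^eps` with
#' `eps ~ Normal(0, intensity_log_sd)`. Peptides shared between proteins
#' receive the summed contribution and list every matching protein.
#'
#' @param truth Output of [generate_proteome()].
#' @param config The same [simulation_config()].
#' @return Tibble: `peptide`, `protein_ids` (`;`-separated), `fraction`
#'   (`mt`/`cp`/`wc`), `replicate`, `intensity`.
#' @export
simulate_observations <- function(truth, config) {
  validate_config(config)
  empty <- tibble::tibble(
    peptide = character(), protein_ids = character(),
    fraction = character(), replicate = integer(), intensity = numeric()
  )
  if (nrow(truth) == 0) {
    return(empty)
  }
  with_seed(config$seed + 1L, {
    pep <- digest_proteome(truth, config$min_peptide_length)
    if (nrow(pep) == 0) {
      return(empty)
    }
    # peptide -> all matching proteins (shared peptides collapse)
    pep_map <- stats::aggregate(
      protein_id ~ peptide, pep,
      FUN = function(x) paste(sort(unique(x)), collapse = ";")
    )
    names(pep_map)[2] <- "protein_ids"
    observable <- pep_map$peptide[
      stats::runif(nrow(pep_map)) < config$detectability
    ]
    pep <- pep[pep$peptide %in% observable, ]
    if (nrow(pep) == 0) {
      return(empty)
    }
    eff <- fraction_effects(truth, config)
    base <- stats::setNames(truth$base_abundance, truth$protein_id)
    nrep <- config$n_replicates_per_fraction
    rows <- vector("list", 3 * nrep)
    k <- 0
    for (fr in c("mt", "cp", "wc")) {
      e <- stats::setNames(eff[[fr]], eff$protein_id)[pep$protein_id]
      present <- e > 0
      for (r in seq_len(nrep)) {
        k <- k + 1
        keep <- present & (stats::runif(nrow(pep)) >= config$missing_rate)
        if (!any(keep)) next
        eps <- stats::rnorm(sum(keep), 0, config$intensity_log_sd)
        rows[[k]] <- tibble::tibble(
          peptide = pep$peptide[keep],
          protein_id = pep$protein_id[keep],
          fraction = fr,
          replicate = r,
          intensity = base[pep$protein_id[keep]] * e[keep] * 10^eps
        )
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) {
      return(empty)
    }
    obs <- dplyr::bind_rows(rows)
    obs <- dplyr::summarise(
      dplyr::group_by(obs, .data$peptide, .data$fraction, .data$replicate),
      intensity = sum(.data$intensity), .groups = "drop"
    )
    obs$protein_ids <- stats::setNames(
      pep_map$protein_ids, pep_map$peptide
    )[obs$peptide]
    obs <- obs[order(obs$peptide, obs$fraction, obs$replicate), ]
    obs[, c("peptide", "protein_ids", "fraction", "replicate", "intensity")]
  })
}

#' Simulate targeting-prediction tables for three transcriptome variants
#'
#' Each transcriptome variant independently truncates the 5' end of each
#' ORF with probability `truncation_prob`; a truncated ORF loses both its
#' start methionine and any targeting signal. Intact ORFs with a signal
#' predict `M`; proteins without a signal occasionally predict `M`
#' spuriously (`targeting_fp_rate`).
#'
#' @param truth Output of [generate_proteome()].
#' @param config The same [simulation_config()].
#' @return Named list of three tibbles (`t1`, `t2`, `t3`) with columns
#'   `name`, `loc` (`M`/`C`/`S`/`_`), `RC` (reliability class 1-5,
#'   parsed downstream but never used as a filter), `start_met`.
#' @export
simulate_targeting_tables <- function(truth, config) {
  validate_config(config)
  with_seed(config$seed + 2L, {
    n <- nrow(truth)
    lapply(stats::setNames(nm = c("t1", "t2", "t3")), function(tx) {
      truncated <- stats::runif(n) < config$truncation_prob
      fp <- stats::runif(n) < config$targeting_fp_rate
      loc <- character(n)
      for (i in seq_len(n)) {
        loc[i] <- if (truth$has_targeting_signal[i]) {
          if (truncated[i]) "_" else "M"
        } else if (fp[i] && !truncated[i]) {
          "M"
        } else if (truth$localization[i] == "chloroplast") {
          if (stats::runif(1) < 0.7) "C" else "S"
        } else {
          "S"
        }
      }
      tibble::tibble(
        name = truth$protein_id,
        loc = loc,
        RC = sample(1:5, n, replace = TRUE),
        start_met = !truncated
      )
    })
  })
}

#' Simulate reference-mitoproteome ortholog tables
#'
#' Links each protein to 0..`n_reference_proteomes` reference
#' mitoproteomes: true mitochondrial (and dual) proteins hit each
#' reference with probability `reference_coverage`; other proteins with
#' probability `ortholog_fp_rate`.
#'
#' @param truth Output of [generate_proteome()].
#' @param config The same [simulation_config()].
#' @return Tibble: `protein_id`, `reference_species`, `reference_protein`.
#' @export
simulate_ortholog_tables <- function(truth, config) {
  validate_config(config)
  species <- reference_species_names(config$n_reference_proteomes)
  with_seed(config$seed + 3L, {
    is_mito <- truth$localization %in% c("mito", "dual")
    out <- lapply(species, function(sp) {
      hit <- stats::runif(nrow(truth)) <
        ifelse(is_mito, config$reference_coverage, config$ortholog_fp_rate)
      if (!any(hit)) {
        return(NULL)
      }
      tibble::tibble(
        protein_id = truth$protein_id[hit],
        reference_species = sp,
        reference_protein = sprintf("%s|%05d", sp, which(hit))
      )
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0) {
      return(tibble::tibble(
        protein_id = character(), reference_species = character(),
        reference_protein = character()
      ))
    }
    res <- dplyr::bind_rows(out)
    res[order(res$protein_id, res$reference_species), ]
  })
}

#' Default reference mitoproteome names
#'
#' @param n Number of references.
#' @return Character vector of species labels.
#' @export
reference_species_names <- function(n = 4) {
  base <- c("A_thaliana", "M_musculus", "S_cerevisiae", "T_brucei")
  if (n <= length(base)) {
    return(base[seq_len(n)])
  }
  c(base, sprintf("reference_%d", seq_len(n - length(base))))
}

#' Simulate target and decoy identification scores
#'
#' Target scores are drawn from Normal(`separation`, 1) and decoy scores
#' from Normal(0, 1); the label is preserved and decoy identifiers carry
#' the `REV__` prefix used in the reversed-database convention.
#'
#' @param n_targets,n_decoys Counts of target and decoy entries.
#' @param separation Mean target-decoy score separation in SD units.
#' @param seed Integer seed.
#' @return Tibble: `id`, `score`, `is_decoy`.
#' @export
simulate_decoy_scores <- function(n_targets, n_decoys, separation, seed = 1L) {
  with_seed(seed, {
    tibble::tibble(
      id = c(
        sprintf("T%06d", seq_len(n_targets)),
        sprintf("REV__D%06d", seq_len(n_decoys))
      ),
      score = c(
        stats::rnorm(n_targets, separation, 1),
        stats::rnorm(n_decoys, 0, 1)
      ),
      is_decoy = rep(c(FALSE, TRUE), c(n_targets, n_decoys))
    )
  })
}

#' Construct an evidence cohort with specified strategy marginals
#'
#' Builds a synthetic per-protein evidence table whose strategy marginal
#' counts, overlap structure, curation counts and chloroplast-greater
#' retention count are set by the caller, so the integration arithmetic
#' can be exercised against printed cohort-level totals when the
#' underlying per-protein data are unavailable. The overlap structure is
#' the minimal one consistent with the marginals: the targeting set is
#' nested inside the ortholog-and-enriched overlap, contaminant removals
#' are drawn from enriched-only members, and reintegrations from
#' candidates outside the union.
#'
#' @param n_candidates Total candidate proteins.
#' @param n_ortholog,n_enriched,n_targeting Per-strategy marginal counts.
#' @param n_overlap_oe Size of the ortholog-and-enriched overlap.
#' @param n_removed Contaminants removed (clear non-mito annotation and
#'   no reference ortholog), taken from enriched-only members.
#' @param n_reintegrated Non-members reintegrated (predicted mitoproteome
#'   membership and mitochondrial functional annotation).
#' @param n_cp_greater Final members with greater chloroplast enrichment
#'   (Mt/Cp < 1), taken from ortholog-only members.
#' @return Tibble of evidence profiles consumable by [strategy_union()]
#'   and [curate()].
#' @export
simulate_evidence_cohort <- function(n_candidates = 2704,
                                     n_ortholog = 994,
                                     n_enriched = 1543,
                                     n_targeting = 77,
                                     n_overlap_oe = 762,
                                     n_removed = 24,
                                     n_reintegrated = 35,
                                     n_cp_greater = 211) {
  n_o_only <- n_ortholog - n_overlap_oe
  n_e_only <- n_enriched - n_overlap_oe
  n_union <- n_o_only + n_e_only + n_overlap_oe
  n_out <- n_candidates - n_union
  stopifnot(
    n_targeting <= n_overlap_oe, n_o_only >= 0, n_e_only >= n_removed,
    n_out >= n_reintegrated, n_cp_greater <= n_o_only
  )
  id <- sprintf("C%05d", seq_len(n_candidates))
  # block layout: [O&E (targeting first)] [O only] [E only] [outside union]
  block <- rep(
    c("oe", "o", "e", "none"),
    c(n_overlap_oe, n_o_only, n_e_only, n_out)
  )
  ortholog <- block %in% c("oe", "o")
  enriched <- block %in% c("oe", "e")
  targeting <- seq_len(n_candidates) <= n_targeting
  clear_nonmito <- rep(FALSE, n_candidates)
  e_only_idx <- which(block == "e")
  clear_nonmito[e_only_idx[seq_len(n_removed)]] <- TRUE
  predicted <- rep(FALSE, n_candidates)
  annotated <- rep(FALSE, n_candidates)
  out_idx <- which(block == "none")
  if (n_reintegrated > 0) {
    predicted[out_idx[seq_len(n_reintegrated)]] <- TRUE
    annotated[out_idx[seq_len(n_reintegrated)]] <- TRUE
  }
  ratio <- ifelse(enriched, 2, 1.2)
  o_only_idx <- which(block == "o")
  ratio[o_only_idx[seq_len(n_cp_greater)]] <- 0.5
  tibble::tibble(
    id = id,
    ortholog_member = ortholog,
    enriched = enriched,
    targeting_consensus = targeting,
    predicted_mito = predicted,
    annotation_mito_function = annotated,
    annotation_clear_nonmito = clear_nonmito,
    ratio_mt_cp = ratio
  )
}
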