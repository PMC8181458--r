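#' Write a genotype set as VCF 4.2
#'
#' Serializes simulated genotypes with synthetic coordinates: every locus on
#' `chr1`, 1-based positions spaced 1 Mb apart, alleles `A`/`G`. The header
#' states loudly that positions are synthetic. INFO fields `P1AF`, `P2AF`,
#' `FSTS` carry the two source-population frequencies of the counted (ALT)
#' allele and the locus F_ST. Genotypes are written unphased (`0/0`, `0/1`,
#' `1/1`); when the genotype set retains its local-ancestry array a second
#' FORMAT field `LA` carries the two haplotypes' ancestries as a two-digit
#' code (e.g. `12` = first haplotype from Population 1, second from
#' Population 2), preserving haplotype order.
#'
#' @param genotypes A `genotype_set` from [sample_genotypes()].
#' @param path Output file path.
#' @param sample_ids Optional sample names (default `ind1..indN`).
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, path, sample_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_set"))
  G <- genotypes$dosages
  fr <- genotypes$freqs
  n <- nrow(G)
  L <- ncol(G)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  stopifnot(length(sample_ids) == n)
  has_la <- !is.null(genotypes$local)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=admixpower",
    paste0("##reference=none (SYNTHETIC coordinates: simulated ",
           "LD-independent loci placed on chr1 at 1 Mb spacing; positions ",
           "do not refer to any genome build)"),
    "##contig=<ID=chr1>",
    paste0("##INFO=<ID=P1AF,Number=1,Type=Float,Description=",
           "\"Population 1 ALT allele frequency\">"),
    paste0("##INFO=<ID=P2AF,Number=1,Type=Float,Description=",
           "\"Population 2 ALT allele frequency\">"),
    paste0("##INFO=<ID=FSTS,Number=1,Type=Float,Description=",
           "\"Locus F_ST between the source populations\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_la) paste0(
      "##FORMAT=<ID=LA,Number=1,Type=String,Description=\"Local ancestry ",
      "of the two haplotypes, in haplotype order, as a two-digit code of ",
      "1 (Population 1) and 2 (Population 2)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )

  gt <- matrix(c("0/0", "0/1", "1/1")[G + 1L], n, L)
  if (has_la) {
    la <- matrix(paste0(genotypes$local[, , 1], genotypes$local[, , 2]), n, L)
    gt <- matrix(paste(gt, la, sep = ":"), n, L)
  }
  records <- vapply(seq_len(L), function(s) {
    paste(c("chr1", format(s * 1000000L, scientific = FALSE),
            paste0("locus", s), "A", "G", ".", "PASS",
            sprintf("P1AF=%.6g;P2AF=%.6g;FSTS=%.6g",
                    fr$p1[s], fr$p2[s], fr$fst[s]),
            if (has_la) "GT:LA" else "GT", gt[, s]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write a cohort's per-individual table as TSV
#'
#' Columns: `individual_id`, `theta_pop1`, `prs_true`, `env_score`,
#' `y_quant`, and `y_binary` for dichotomous traits.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  ph <- cohort$phenotype
  df <- data.frame(individual_id = paste0("ind", seq_along(cohort$theta)),
                   theta_pop1 = cohort$theta, prs_true = ph$prs,
                   env_score = ph$env, y_quant = ph$y_quant)
  if (!is.null(ph$y_binary)) df$y_binary <- ph$y_binary
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association table as TSV
#'
#' Columns: `locus_id`, `is_causal`, `beta_hat`, `se`, `p_value`, `tested`,
#' `population`.
#'
#' @param tab An `assoc_table` from [assoc_scan()].
#' @param path Output file path.
#' @param causal_idx Causal locus indices (for the `is_causal` column).
#' @param population Label for the scanned cohort.
#' @return The path, invisibly.
#' @export
write_assoc_tsv <- function(tab, path, causal_idx = integer(0),
                            population = NA_character_) {
  stopifnot(inherits(tab, "assoc_table"))
  df <- data.frame(locus_id = paste0("locus", tab$locus),
                   is_causal = tab$locus %in% causal_idx,
                   beta_hat = tab$beta, se = tab$se, p_value = tab$p,
                   tested = tab$tested, population = population)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration (and its hash), master seed, package version,
#' timestamps, and the output files produced, as JSON. The manifest is
#' written atomically (temp file then rename), and a run can be reproduced
#' bitwise from its config and seed.
#'
#' @param config Configuration list used for the run.
#' @param seed Master seed.
#' @param outputs Character vector of output file paths.
#' @param path Manifest path.
#' @param started Start time (`POSIXct`), default now.
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, seed, outputs, path,
                           started = Sys.time()) {
  manifest <- list(
    config = config,
    config_hash = config_hash(config),
    master_seed = seed,
    package_version = as.character(utils::packageVersion("admixpower")),
    r_version = R.version.string,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Hash a configuration list
#'
#' FNV-1a hash of the canonical JSON serialization, as a hex string. Used in
#' run manifests to detect configuration drift.
#'
#' @param config Configuration list.
#' @return Character scalar (8 hex digits).
#' @export
config_hash <- function(config) {
  txt <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA, null = "null"))
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor_dbl(h, code)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
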