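# Readers, writers and the end-to-end pipeline driver.

#' Read a genes x samples abundance table
#'
#' First column gene ids, header row sample ids. Missing values are handled
#' per `missing`: `"drop_gene"` removes genes with any NA (logged),
#' `"zero"` imputes 0.
#'
#' @param path TSV or CSV file.
#' @param fmt `"tsv"` or `"csv"`; default guessed from the extension.
#' @param missing `"drop_gene"` (default) or `"zero"`.
#' @return Numeric matrix with gene id rownames and sample id colnames.
#' @export
read_abundance <- function(path, fmt = NULL, missing = c("drop_gene", "zero")) {
  missing <- match.arg(missing)
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (fmt == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("abundance table needs a gene id column and at least one sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in abundance table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))
      stop("non-numeric value in abundance table at row ", bad[1L] + 1L,
           ", column '", names(vals)[j], "'")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    if (missing == "drop_gene") {
      drop <- rowSums(is.na(m)) > 0
      message("dropping ", sum(drop), " gene(s) with missing values")
      m <- m[!drop, , drop = FALSE]
    } else {
      m[is.na(m)] <- 0
    }
  }
  if (any(m < 0)) stop("negative abundances not allowed")
  m
}

#' Read a sample label table
#'
#' Two-column TSV (sample_id, label), with or without a header line.
#'
#' @param path TSV file.
#' @return Named character vector mapping sample ids to labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label table needs two columns: sample_id, label")
  if (identical(tolower(df[1L, 1L]), "sample_id")) df <- df[-1L, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields set_id, description,
#' then member gene ids. Members are de-duplicated within a set with a
#' warning.
#'
#' @param path GMT file.
#' @return Named list of character vectors; descriptions kept as attribute
#'   `descriptions`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene-set file: ", path)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("set '", fields[1L], "': duplicated members stored once")
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
    desc[fields[1L]] <- fields[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (default "na").
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}

#' Write sequences to FASTA
#'
#' @param x A `cds_set` or named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "cds_set")) x$sequences else x
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
}

#' Write a composition profile as TSV
#'
#' Columns: gene_id, the 61 codon percentages in fixed alphabetical order,
#' gc3_pct, au3_pct, n_codons. Values serialized with 6 significant digits
#' (configurable) so repeated runs are byte-comparable.
#'
#' @param profile A `composition_profile`.
#' @param path Output file.
#' @param digits Significant digits (default 6).
#' @export
write_profile_tsv <- function(profile, path, digits = 6) {
  df <- data.frame(gene_id = rownames(profile$pct),
                   signif(profile$pct, digits),
                   gc3_pct = signif(profile$gc3_pct, digits),
                   au3_pct = signif(profile$au3_pct, digits),
                   n_codons = profile$n_codons,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a composition profile written by [write_profile_tsv()]
#'
#' @param path TSV file.
#' @return A `composition_profile` (without count provenance).
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  pct <- as.matrix(df[, SENSE_CODONS, drop = FALSE])
  rownames(pct) <- df$gene_id
  structure(list(pct = pct,
                 gc3_pct = stats::setNames(df$gc3_pct, df$gene_id),
                 au3_pct = stats::setNames(df$au3_pct, df$gene_id),
                 n_codons = stats::setNames(df$n_codons, df$gene_id),
                 n_sense = NULL, n_stop = NULL, gc3_denominator = "all"),
            class = "composition_profile")
}

write_matrix_tsv <- function(m, path, digits = 6, id_col = "id") {
  df <- data.frame(rownames(m), signif(m, digits), check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Pipeline configuration
#'
#' Collects the stage parameters of [run_pipeline()]. Either paths to real
#' inputs (`fasta`, `abundance`, `labels`, `gmt`) or `synthetic = TRUE`
#' (default), in which case the bundled generator supplies genome, gene sets
#' and cohort from the master seed.
#'
#' @param out_dir Output directory.
#' @param fasta,abundance,labels,gmt Optional input paths.
#' @param synthetic Generate inputs when paths are absent (default TRUE).
#' @param seed Master seed.
#' @param n_genes Synthetic genome size (default 1000).
#' @param n_perm Enrichment permutations (default 500).
#' @param fdr_cut Enrichment FDR threshold (default 0.01).
#' @param n_reps Diagnostic cross-validation repetitions (default 200).
#' @param train_frac Training fraction (default 0.8).
#' @param transform Abundance transform (default "log2p1").
#' @param epsilon Employment-shift exclusion floor (default 0.01).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, fasta = NULL, abundance = NULL,
                            labels = NULL, gmt = NULL, synthetic = TRUE,
                            seed = 1, n_genes = 1000, n_perm = 500,
                            fdr_cut = 0.01, n_reps = 200, train_frac = 0.8,
                            transform = "log2p1", epsilon = 0.01) {
  for (p in c(fasta, abundance, labels, gmt)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (!synthetic && is.null(fasta)) stop("non-synthetic runs need a FASTA")
  structure(list(out_dir = out_dir, fasta = fasta, abundance = abundance,
                 labels = labels, gmt = gmt, synthetic = synthetic,
                 seed = seed, n_genes = n_genes, n_perm = n_perm,
                 fdr_cut = fdr_cut, n_reps = n_reps, train_frac = train_frac,
                 transform = transform, epsilon = epsilon),
            class = "pipeline_config")
}

#' Run the full codon-employment analysis pipeline
#'
#' Stages: composition profiling, GC3 ranking + enrichment + GP1/GP2
#' derivation (when gene sets are available), cohort CECs + employment shift
#' + CorrCEC (when a labelled cohort is available), and the cross-validated
#' diagnostics. Every artifact is a TSV under `out_dir`; `manifest.json`
#' records inputs, parameters, seeds and MD5 checksums of all outputs, so a
#' rerun with the same config is verifiably identical.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                   stages = list(), outputs = list())
  res <- list()

  # stage: inputs
  if (!is.null(config$fasta)) {
    cds <- read_cds(config$fasta)
    truth <- NULL
    sets <- if (!is.null(config$gmt)) read_gene_sets(config$gmt) else NULL
  } else {
    genome <- generate_cds_set(genome_spec(n_genes = config$n_genes,
                                           seed = config$seed))
    cds <- genome$cds
    truth <- genome$truth
    sets <- generate_gene_sets(truth, seed = config$seed + 1)
    write_fasta(cds, file.path(config$out_dir, "synthetic_genome.fa"))
    write_gene_sets(sets, file.path(config$out_dir, "synthetic_sets.gmt"))
  }
  manifest$stages$inputs <- "completed"

  # stage: composition
  counts <- count_codons(cds)
  profile <- composition_profile(counts)
  write_profile_tsv(profile, file.path(config$out_dir, "profiles.tsv"))
  summ <- gc3_distribution_summary(profile)
  res$profile <- profile
  res$gc3_summary <- summ
  manifest$stages$composition <- "completed"

  # stage: enrichment
  gp1 <- gp2 <- NULL
  if (!is.null(sets)) {
    ranked <- rank_by_gc3(profile)
    enr <- preranked_enrichment(ranked, sets, n_perm = config$n_perm,
                                seed = config$seed + 2)
    groups <- derive_groups(enr, fdr_cut = config$fdr_cut)
    gp1 <- groups$gp1
    gp2 <- groups$gp2
    enr_out <- enr
    enr_out$leading_edge <- vapply(enr$leading_edge, paste, character(1L),
                                   collapse = ",")
    utils::write.table(enr_out, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(gp1, file.path(config$out_dir, "gp1_genes.txt"))
    writeLines(gp2, file.path(config$out_dir, "gp2_genes.txt"))
    res$enrichment <- enr
    res$groups <- groups
    manifest$stages$enrichment <- "completed"
  } else {
    manifest$stages$enrichment <- "skipped (no gene sets)"
  }

  # stage: cohort
  if (!is.null(config$abundance)) {
    abundance <- read_abundance(config$abundance)
    labels <- read_labels(config$labels)
  } else if (config$synthetic) {
    cohort <- generate_cohort(truth, cohort_spec(seed = config$seed + 3))
    abundance <- cohort$abundance
    labels <- cohort$labels
    write_matrix_tsv(abundance, file.path(config$out_dir, "synthetic_cohort.tsv"),
                     id_col = "gene_id")
    utils::write.table(data.frame(sample_id = names(labels), label = labels),
                       file.path(config$out_dir, "synthetic_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    abundance <- NULL
  }
  if (!is.null(abundance)) {
    ctrl <- cohort_cec(profile, abundance, labels, "control",
                       transform = config$transform)
    dis <- cohort_cec(profile, abundance, labels, "disease",
                      transform = config$transform)
    shift <- employment_shift(ctrl, dis, epsilon = config$epsilon)
    cc <- corrcec(profile, ctrl, dis)
    shift_df <- data.frame(codon = SENSE_CODONS,
                           control_cec = signif(ctrl$mean, 6),
                           disease_cec = signif(dis$mean, 6),
                           rel_change_pct = signif(shift$per_codon, 6),
                           group = ifelse(SENSE_CODONS %in% GC3_CODONS,
                                          "GC3", "AU3"))
    utils::write.table(shift_df, file.path(config$out_dir, "employment_shift.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(cc[1L], signif(cc[-1L], 6)),
                       file.path(config$out_dir, "corrcec.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$control_cec <- ctrl
    res$disease_cec <- dis
    res$shift <- shift
    res$corrcec <- cc
    manifest$stages$cec <- "completed"

    subset <- if (!is.null(gp1) && length(gp1) >= 3) gp1 else NULL
    perf <- cross_validated_diagnostics(profile, abundance, labels,
                                        subset = subset,
                                        train_frac = config$train_frac,
                                        n_reps = config$n_reps,
                                        seed = config$seed + 4,
                                        transform = config$transform)
    perf_df <- data.frame(metric = c("sensitivity", "specificity"),
                          mean = signif(c(perf$sensitivity$mean,
                                          perf$specificity$mean), 6),
                          sd = signif(c(perf$sensitivity$sd,
                                        perf$specificity$sd), 6))
    utils::write.table(perf_df, file.path(config$out_dir, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$diagnostics <- perf
    manifest$stages$diagnostics <- "completed"
  } else {
    manifest$stages$cec <- "skipped (no abundance data)"
    manifest$stages$diagnostics <- "skipped (no abundance data)"
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(f) list(md5 = unname(tools::md5sum(f))))
  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
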