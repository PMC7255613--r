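## End-to-end orchestration: encode -> (train | load) -> predict -> GTS ->
## enrichment, with a reproducible run manifest.

## FNV-1a hash of a character string, as 8 hex digits.  The xor only ever
## touches the low byte, which keeps everything inside exact double
## arithmetic (R's bitwXor cannot take values above 2^31).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    ## multiply mod 2^32 in two 16-bit halves to stay inside exact doubles
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the scoring pipeline end to end
#'
#' Reads alignments, annotations and variants, encodes feature windows,
#' trains the classifier (or loads a checkpoint), scores the variants,
#' aggregates a gene tolerance (GTS) table from the scored catalog, and
#' writes per-MAF-category enrichment statistics, all under one output
#' directory with a run manifest.
#'
#' @param config Named list, or path to a JSON file, with elements:
#'   `alignment_dir` (per-gene `<gene>.fasta` files), `annotations`
#'   (TSV path, optional), `variants` (labeled training TSV, optional if
#'   `model` given), `catalog` (MAF catalog TSV, optional),
#'   `gene_lengths` (TSV path; defaults to alignment lengths), `model`
#'   (checkpoint path to load instead of training), `out_dir`, `seed`,
#'   `network` (list of [deepsav_config()] overrides), `mask` (list of
#'   [feature_mask()] switches), `rare_maf_cutoff` (default 1e-4),
#'   `deleterious_threshold` (default 0.75), `overwrite` (default FALSE).
#' @return Invisibly, a list with the fitted model, scored variants, gene
#'   tolerance table, enrichment matrix and manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  need <- function(nm) {
    if (is.null(config[[nm]])) {
      stop("pipeline config is missing '", nm, "'", call. = FALSE)
    }
    config[[nm]]
  }
  out_dir <- need("out_dir")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 &&
      !isTRUE(config$overwrite)) {
    stop("output directory ", out_dir,
         " is not empty; set overwrite=true to replace it", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  rare_cut <- if (is.null(config$rare_maf_cutoff)) 1e-4 else
    config$rare_maf_cutoff
  del_thr <- if (is.null(config$deleterious_threshold)) 0.75 else
    config$deleterious_threshold

  ## --- load gene data ---
  aln_dir <- need("alignment_dir")
  aln_files <- list.files(aln_dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(aln_files) == 0L) {
    stop("no .fasta alignments found in ", aln_dir, call. = FALSE)
  }
  gene_ids <- sub("\\.fasta$", "", basename(aln_files))
  annotations <- if (!is.null(config$annotations) &&
                     file.exists(config$annotations)) {
    read_annotations_tsv(config$annotations)
  } else {
    if (!is.null(config$annotations)) {
      warning("annotation file ", config$annotations,
              " not found; imputing zero annotations", call. = FALSE)
    }
    list()
  }
  genes <- stats::setNames(vector("list", length(gene_ids)), gene_ids)
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    prof <- estimate_profile(read_alignment(aln_files[i]))
    ann <- annotations[[g]]
    genes[[g]] <- withCallingHandlers(
      gene_data(g, prof, ann),
      warning = function(w) {
        message("note: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  lengths <- if (!is.null(config$gene_lengths)) {
    read_gene_lengths_tsv(config$gene_lengths)
  } else {
    data.frame(gene = gene_ids,
               protein_len = vapply(genes, function(g) g$length, integer(1)))
  }

  mask <- if (!is.null(config$mask)) do.call(feature_mask, config$mask) else
    NULL
  net_cfg <- do.call(deepsav_config,
                     c(config$network,
                       if (is.null(config$network$seed)) list(seed = seed)))

  ## --- model: train or load ---
  if (!is.null(config$model)) {
    model <- load_deepsav(config$model)
  } else {
    variants <- read_variants_tsv(need("variants"))
    if (!"label" %in% names(variants)) {
      stop("training variants need a 'label' column (or supply 'model')",
           call. = FALSE)
    }
    x <- encode_dataset(genes, variants, mask = mask)
    model <- deepsav_fit(x, variants$label, net_cfg)
    save_deepsav(model, file.path(out_dir, "model.rds"))
  }

  result <- list(model = model, genes = genes)

  ## --- score the catalog and derive gene-level outputs ---
  if (!is.null(config$catalog)) {
    catalog <- read_variants_tsv(config$catalog)
    xc <- encode_dataset(genes, catalog, mask = mask)
    catalog$deepsav_score <- predict(model, xc)
    write_variants_tsv(catalog, file.path(out_dir, "scored_catalog.tsv"))
    tol <- gene_tolerance_table(catalog, lengths,
                                rare_maf_cutoff = rare_cut,
                                score_threshold = del_thr)
    write_gene_tolerance_tsv(tol, file.path(out_dir, "gene_tolerance.tsv"))
    ptab <- position_property_table(genes)
    cat_lab <- maf_category(catalog$maf)
    subsets <- split(catalog[, c("gene", "position")], cat_lab)
    enr <- enrichment_matrix(ptab, subsets)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$catalog <- catalog
    result$tolerance <- tol
    result$enrichment <- enr
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("deepsav")),
    seed = seed,
    config = config,
    config_hash = fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
    outputs = list.files(out_dir),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
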