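#' Phased haplotype panel
#'
#' @param haps Integer matrix (haplotypes x SNPs) of 0/1 allele codes with
#'   SNP ids as column names.
#' @param sites Data frame with one row per SNP: `id`, `chrom`, `pos`
#'   (1-based), `allele1` (the base coded 1), `allele0` (the base coded 0).
#' @return Object of class `hap_panel`.
#' @export
hap_panel <- function(haps, sites) {
  if (!is.matrix(haps)) haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (is.null(colnames(haps)))
    stop("haplotype matrix must carry SNP ids as column names", call. = FALSE)
  if (!all(haps %in% c(0L, 1L)))
    stop("haplotype matrix entries must be 0/1", call. = FALSE)
  need <- c("id", "chrom", "pos", "allele1", "allele0")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop("sites needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!identical(colnames(haps), as.character(sites$id)))
    stop("sites rows must match haplotype matrix columns (same ids, same order)",
         call. = FALSE)
  rownames(sites) <- NULL
  structure(list(haps = haps, sites = sites), class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d haplotypes x %d SNPs on %d chromosome(s)\n",
              nrow(x$haps), ncol(x$haps), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Allele frequency of the 1-coded allele for each panel SNP
#' @param panel A [hap_panel()].
#' @return Named numeric vector.
#' @export
panel_freqs <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  colMeans(panel$haps)
}

#' Combine panels sharing the same haplotype rows
#' @param ... `hap_panel` objects with equal haplotype counts.
#' @return A single `hap_panel`.
#' @export
bind_panels <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1L]]) && !inherits(ps[[1L]], "hap_panel"))
    ps <- ps[[1L]]
  stopifnot(all(vapply(ps, inherits, logical(1), "hap_panel")))
  n <- unique(vapply(ps, function(p) nrow(p$haps), integer(1)))
  if (length(n) != 1L)
    stop("panels must have identical haplotype counts", call. = FALSE)
  hap_panel(do.call(cbind, lapply(ps, `[[`, "haps")),
            do.call(rbind, lapply(ps, `[[`, "sites")))
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS marker table
#'
#' Expects a TSV with header columns `id`, `chrom`, `pos`, `risk_allele`,
#' `other_allele`, `odds_ratio`, `p_value`, `source`
#' (`primary_scan`/`catalog`) and `disease`. Every row is validated; the
#' error message names the first offending row.
#'
#' @param path Path to the TSV file.
#' @return Data frame of markers with normalised types.
#' @export
read_marker_table <- function(path) {
  req <- c("id", "chrom", "pos", "risk_allele", "other_allele",
           "odds_ratio", "p_value", "source", "disease")
  df <- read_tsv_checked(path, req, "marker table")
  df <- df[req]
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  suppressWarnings({
    df$pos <- as.integer(df$pos)
    df$odds_ratio <- as.numeric(df$odds_ratio)
    df$p_value <- as.numeric(df$p_value)
  })
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i))
      stop("marker table '", path, "', row ", i[1L], ": ", msg, call. = FALSE)
  }
  bad_row(is.na(df$pos) | df$pos < 1, "pos must be a positive integer")
  bad_row(is.na(df$odds_ratio) | df$odds_ratio <= 0,
          "odds_ratio must be numeric and > 0")
  bad_row(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1,
          "p_value must lie in (0, 1]")
  bad_row(!df$source %in% c("primary_scan", "catalog"),
          "source must be 'primary_scan' or 'catalog'")
  bad_row(df$risk_allele == df$other_allele,
          "risk_allele must differ from other_allele")
  dup <- duplicated(df$id)
  if (any(dup))
    stop("marker table '", path, "': duplicate marker id '",
         df$id[which(dup)[1L]], "'", call. = FALSE)
  df
}

#' Write a GWAS marker table
#' @param markers Data frame as returned by [read_marker_table()].
#' @param path Output TSV path.
#' @export
write_marker_table <- function(markers, path) write_tsv(markers, path)

#' Read a phased haplotype panel
#'
#' Two formats are supported. A VCF (`.vcf` extension) with phased `GT`
#' fields: each sample contributes two haplotype rows and the ALT allele is
#' coded 1; any unphased genotype is an error. Otherwise a haplotype-matrix
#' TSV with a header of SNP ids, one row per haplotype, entries 0/1; site
#' metadata (chrom, pos, alleles) is read from `<path>.sites` when present.
#'
#' @param path Panel file path.
#' @param sites_path Optional explicit path to the site metadata TSV
#'   (columns `id`, `chrom`, `pos`, `allele1`, `allele0`).
#' @return A [hap_panel()].
#' @export
read_haplotype_panel <- function(path, sites_path = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(read_panel_vcf(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("haplotype matrix '", path, "' needs a header and >= 1 row",
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged haplotype matrix '", path, "': line ",
         which(widths != widths[1L])[1L], " has ",
         widths[which(widths != widths[1L])[1L]], " fields, expected ",
         widths[1L], call. = FALSE)
  ids <- fields[[1L]]
  body <- fields[-1L]
  haps <- matrix(suppressWarnings(as.integer(unlist(body))),
                 nrow = length(body), byrow = TRUE,
                 dimnames = list(NULL, ids))
  if (anyNA(haps) || !all(haps %in% c(0L, 1L)))
    stop("haplotype matrix '", path, "' must contain only 0/1 entries",
         call. = FALSE)
  if (is.null(sites_path)) sites_path <- paste0(path, ".sites")
  if (file.exists(sites_path)) {
    sites <- read_tsv_checked(sites_path,
                              c("id", "chrom", "pos", "allele1", "allele0"),
                              "panel sites table")
    sites$id <- as.character(sites$id)
    sites <- sites[match(ids, sites$id), , drop = FALSE]
    if (anyNA(sites$id))
      stop("panel sites table lacks entries for some SNPs in '", path, "'",
           call. = FALSE)
  } else {
    sites <- data.frame(id = ids, chrom = NA_character_, pos = NA_integer_,
                        allele1 = "A", allele0 = "G",
                        stringsAsFactors = FALSE)
  }
  hap_panel(haps, sites)
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))      # single-variant files drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v)
  gt <- matrix(as.character(gt), nrow = nrow(fix),
               dimnames = list(as.character(fix[, "ID"]), colnames(gt)))
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    bad <- arrayInd(which(unphased)[1L], dim(gt))
    stop("unphased genotype in VCF '", path, "' at SNP ",
         rownames(gt)[bad[1L]], ", sample ", colnames(gt)[bad[2L]],
         call. = FALSE)
  }
  split_gt <- function(col) {
    parts <- strsplit(col, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("VCF '", path, "' must contain diploid phased genotypes",
           call. = FALSE)
    m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
    if (anyNA(m) || !all(m %in% c(0L, 1L)))
      stop("VCF '", path, "' must be biallelic with 0/1 alleles",
           call. = FALSE)
    m
  }
  per_sample <- lapply(seq_len(ncol(gt)), function(j) split_gt(gt[, j]))
  # two haplotype rows per sample, SNPs in columns
  haps <- do.call(rbind, lapply(per_sample, function(m) t(m)))
  colnames(haps) <- as.character(fix[, "ID"])
  sites <- data.frame(id = as.character(fix[, "ID"]),
                      chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      allele1 = as.character(fix[, "ALT"]),
                      allele0 = as.character(fix[, "REF"]),
                      stringsAsFactors = FALSE)
  hap_panel(haps, sites)
}

#' Write a haplotype panel as matrix TSV plus sites file
#' @param panel A [hap_panel()].
#' @param path Output path for the matrix; sites go to `<path>.sites`.
#' @export
write_haplotype_panel <- function(panel, path) {
  stopifnot(inherits(panel, "hap_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(panel$haps), collapse = "\t"), con)
  utils::write.table(panel$haps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(panel$sites, paste0(path, ".sites"))
  invisible(path)
}

#' Gene model with exon structure
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame or two-column matrix of exon `start`, `end`
#'   (1-based inclusive, genomic coordinates, ascending, non-overlapping).
#' @param is_mhc Whether the gene lies in the MHC region.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, is_mhc = FALSE) {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end))
    stop("gene ", gene_id, ": exon start > end", call. = FALSE)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("gene ", gene_id, ": exons overlap", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": strand must be '+' or '-'", call. = FALSE)
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand,
                 exons = exons[c("start", "end")], is_mhc = isTRUE(is_mhc)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exon(s), %d-%d\n", x$gene_id,
              x$chrom, x$strand, nrow(x$exons), min(x$exons$start),
              max(x$exons$end)))
  invisible(x)
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 (`.bed`): one line per gene, exon structure from the block fields.
#' GFF3 (`.gff`/`.gff3`): only `exon` features are used, grouped by their
#' `Parent` attribute; exactly one transcript per gene is required, so the
#' `Parent` id is taken as the gene id.
#'
#' @param path Gene model file.
#' @return List of [gene_model()] objects, named by gene id.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    models <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      blocks <- g$blocks[[1L]]
      if (is.null(blocks) || length(blocks) == 0L) {
        ex <- data.frame(start = BiocGenerics::start(g),
                         end = BiocGenerics::end(g))
      } else {
        # BED12 blocks are 1-based relative to the feature start
        ex <- data.frame(
          start = BiocGenerics::start(g) + BiocGenerics::start(blocks) - 1L,
          end = BiocGenerics::start(g) + BiocGenerics::end(blocks) - 1L)
      }
      gene_model(gene_id = g$name,
                 chrom = as.character(GenomicRanges::seqnames(g)),
                 strand = as.character(BiocGenerics::strand(g)),
                 exons = ex)
    })
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L)
      stop("no exon features in '", path, "'", call. = FALSE)
    parent <- vapply(gr$Parent, function(p) as.character(p)[1L], character(1))
    models <- lapply(split(seq_along(gr), parent), function(idx) {
      g <- gr[idx]
      gene_model(gene_id = parent[idx[1L]],
                 chrom = as.character(GenomicRanges::seqnames(g))[1L],
                 strand = as.character(BiocGenerics::strand(g))[1L],
                 exons = data.frame(start = BiocGenerics::start(g),
                                    end = BiocGenerics::end(g)))
    })
  } else {
    stop("unsupported gene model format: .", ext,
         " (use BED12 or GFF3)", call. = FALSE)
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

#' Write gene models as BED12
#' @param models List of [gene_model()] objects.
#' @param path Output BED path.
#' @export
write_gene_models <- function(models, path) {
  lines <- vapply(models, function(g) {
    s <- min(g$exons$start); e <- max(g$exons$end)
    sizes <- g$exons$end - g$exons$start + 1L
    starts0 <- g$exons$start - s
    paste(g$chrom, s - 1L, e, g$gene_id, 0L, g$strand, s - 1L, e, 0L,
          nrow(g$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts0, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Flag gene models inside the configured MHC interval
#' @param models List of [gene_model()] objects.
#' @param config A [mech_config()].
#' @return The list with `is_mhc` set on overlapping genes.
#' @export
flag_mhc_genes <- function(models, config) {
  iv <- config$mhc_interval
  lapply(models, function(g) {
    g$is_mhc <- g$chrom == iv$chrom &&
      min(g$exons$start) <= iv$end && max(g$exons$end) >= iv$start
    g
  })
}

#' Read a genetic map
#'
#' Accepts either a PLINK-style MAP file (four whitespace-separated columns:
#' chrom, snp id, cM, bp; no header) or a three-column TSV with header
#' `chrom`, `bp`, `cM`. Within each chromosome the cM coordinate must be
#' non-decreasing in bp and at least two anchor points are required.
#'
#' @param path Map file path.
#' @return Data frame of class `genetic_map` with columns `chrom`, `bp`,
#'   `cM`, sorted by chromosome and position.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("chrom", first, ignore.case = TRUE)) {
    df <- read_tsv_checked(path, c("chrom", "bp", "cM"), "genetic map")
    df <- df[c("chrom", "bp", "cM")]
  } else {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) != 4L)
      stop("PLINK MAP file '", path, "' must have 4 columns", call. = FALSE)
    df <- data.frame(chrom = as.character(raw[[1L]]), bp = raw[[4L]],
                     cM = raw[[3L]], stringsAsFactors = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$bp <- as.numeric(df$bp)
  df$cM <- as.numeric(df$cM)
  if (anyNA(df$bp) || anyNA(df$cM))
    stop("genetic map '", path, "' has non-numeric coordinates",
         call. = FALSE)
  df <- df[order(df$chrom, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("genetic map: chromosome ", ch, " needs >= 2 anchor points",
           call. = FALSE)
    if (any(diff(sub$cM) < 0))
      stop("genetic map: decreasing cM on chromosome ", ch, call. = FALSE)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Write a genetic map as three-column TSV
#' @param map A `genetic_map`.
#' @param path Output path.
#' @export
write_genetic_map <- function(map, path) write_tsv(as.data.frame(map), path)

#' Read eQTL study tables
#'
#' Each file is a TSV with columns `snp_id`, `gene_id` and optionally
#' `direction` (`up`/`down`/`unknown`) and `study_id`; when `study_id` is
#' absent the file's base name is used. Duplicate (snp, gene, study) rows
#' are an error.
#'
#' @param paths Character vector of file paths.
#' @param study_ids Optional study ids, one per file.
#' @return Data frame with columns `snp_id`, `gene_id`, `study_id`,
#'   `direction`.
#' @export
read_eqtl_tables <- function(paths, study_ids = NULL) {
  if (is.null(study_ids))
    study_ids <- tools::file_path_sans_ext(basename(paths))
  stopifnot(length(study_ids) == length(paths))
  recs <- mapply(function(p, sid) {
    df <- read_tsv_checked(p, c("snp_id", "gene_id"), "eQTL table")
    if (is.null(df$direction)) df$direction <- "unknown"
    if (is.null(df$study_id)) df$study_id <- sid
    df[c("snp_id", "gene_id", "study_id", "direction")]
  }, paths, study_ids, SIMPLIFY = FALSE)
  out <- do.call(rbind, recs)
  out[] <- lapply(out, as.character)
  if (!all(out$direction %in% c("up", "down", "unknown")))
    stop("eQTL direction must be up, down or unknown", call. = FALSE)
  key <- paste(out$snp_id, out$gene_id, out$study_id)
  if (anyDuplicated(key))
    stop("duplicate eQTL record: ", key[anyDuplicated(key)], call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a missense impact annotation table
#'
#' TSV with columns `snp_id`, `gene_id`, `impact` (`high`/`low`).
#' @param path File path.
#' @return Data frame.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_checked(path, c("snp_id", "gene_id", "impact"),
                         "missense annotation table")
  df <- df[c("snp_id", "gene_id", "impact")]
  df[] <- lapply(df, as.character)
  bad <- which(!df$impact %in% c("high", "low"))
  if (length(bad))
    stop("annotation table '", path, "', row ", bad[1L],
         ": impact must be 'high' or 'low'", call. = FALSE)
  df
}

#' Read an auxiliary splicing score table
#'
#' TSV with columns `snp_id`, `gene_id`, `site_type` (`donor`/`acceptor`),
#' `signed_distance` (bases from the splice site, negative = exonic side,
#' |distance| <= 80) and `score_change`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_splice_scores <- function(path) {
  df <- read_tsv_checked(path, c("snp_id", "gene_id", "site_type",
                                 "signed_distance", "score_change"),
                         "splice score table")
  df <- df[c("snp_id", "gene_id", "site_type", "signed_distance",
             "score_change")]
  df$snp_id <- as.character(df$snp_id)
  df$gene_id <- as.character(df$gene_id)
  df$site_type <- as.character(df$site_type)
  df$signed_distance <- as.integer(df$signed_distance)
  df$score_change <- as.numeric(df$score_change)
  bad <- which(!df$site_type %in% c("donor", "acceptor"))
  if (length(bad))
    stop("splice score table '", path, "', row ", bad[1L],
         ": site_type must be 'donor' or 'acceptor'", call. = FALSE)
  bad <- which(is.na(df$signed_distance) | abs(df$signed_distance) > 80)
  if (length(bad))
    stop("splice score table '", path, "', row ", bad[1L],
         ": |signed_distance| must be <= 80", call. = FALSE)
  df
}

#' Read a protein relevance table
#'
#' TSV with columns `gene_id`, `disease`, `relevance` (`A`/`B`/`C`/`D`) and
#' `known` (TRUE/FALSE): curated disease-relevance labels supplied as
#' input, never inferred by the pipeline.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_relevance_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "disease", "relevance", "known"),
                         "relevance table")
  df <- df[c("gene_id", "disease", "relevance", "known")]
  df$gene_id <- as.character(df$gene_id)
  df$disease <- as.character(df$disease)
  df$relevance <- as.character(df$relevance)
  df$known <- as.logical(df$known)
  if (!all(df$relevance %in% c("A", "B", "C", "D")))
    stop("relevance labels must be A, B, C or D", call. = FALSE)
  if (anyNA(df$known))
    stop("relevance table 'known' column must be logical", call. = FALSE)
  df
}

#' Write pipeline results and a run manifest
#'
#' Emits one TSV per result table plus `manifest.json` recording the full
#' effective configuration, the RNG seed and per-table record counts. Two
#' runs with equal configuration and seed produce byte-identical files.
#'
#' @param results Result list from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param config The [mech_config()] used.
#' @param seed The RNG seed used.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir, config = mech_config(),
                         seed = config$rng_seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("loci", "candidates", "consensus_eqtls", "mechanism_calls",
              "locus_summaries", "protein_mechanisms", "enrichment",
              "overlaps")
  paths <- character(0)
  counts <- list()
  for (nm in tables) {
    if (is.null(results[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(results[[nm]], p)
    paths <- c(paths, p)
    counts[[nm]] <- nrow(results[[nm]])
  }
  manifest <- list(package = "mechanista",
                   seed = as.integer(seed),
                   config = config_as_list(config),
                   record_counts = counts)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}

#' Read back a report directory
#' @param dir Directory written by [write_report()].
#' @return List of data frames plus `manifest`.
#' @export
read_report <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, function(p)
    utils::read.delim(p, stringsAsFactors = FALSE))
  names(out) <- tools::file_path_sans_ext(basename(files))
  mp <- file.path(dir, "manifest.json")
  if (file.exists(mp)) out$manifest <- jsonlite::read_json(mp)
  out
}
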