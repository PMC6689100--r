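# Plain-text serialization of the fixture bundle and the pipeline's
# standard formats: BED3/BED4 (0-based half-open), TSV matrices with a
# feature_id header column, minimal VCF 4.2 with a GT field, FASTA
# contexts, and JASPAR-style PWM text.  Doubles are written with 17
# significant digits so that write followed by read reproduces values
# exactly.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write intervals as BED
#'
#' @param df Data frame with \code{start}, \code{end} and optionally a
#'   name column (4th BED column).
#' @param path Output path.
#' @param contig Contig name (default "chrS").
#' @param name_col Optional column to use as the BED name field.
#' @export
write_bed <- function(df, path, contig = "chrS", name_col = NULL) {
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- data.frame(contig = contig, start = df$start, end = df$end)
  if (!is.null(name_col)) out$name <- df[[name_col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED3/BED4 file
#'
#' @param path Input path.
#' @return Data frame \code{contig, start, end} and \code{name} when a
#'   4th column is present; 0-based half-open coordinates.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

write_matrix_tsv <- function(M, path, id_col = "feature_id") {
  df <- data.frame(id = colnames(M), t(M), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_matrix_tsv <- function(path, id_col = "feature_id") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[id_col]]
  M <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(M) <- ids
  M
}

write_df_tsv <- function(df, path) {
  d <- df
  num <- vapply(d, function(x) is.numeric(x) && !is.integer(x), logical(1))
  d[num] <- lapply(d[num], fmt_num)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_df_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a dosage matrix as minimal VCF 4.2
#'
#' One line per SNP with a GT field per sample; dosage counts copies of
#' the alternative allele.
#'
#' @param G Dosage matrix (samples x SNPs), NA allowed.
#' @param snps Data frame \code{snp, pos, ref, alt} (0-based positions).
#' @param path Output path.
#' @param contig Contig name.
#' @export
write_vcf <- function(G, snps, path, contig = "chrS") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", contig),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(G)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  ord <- order(snps$pos)
  for (i in ord) {
    g <- G[, snps$snp[i]]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(contig, snps$pos[i] + 1L, snps$snp[i],
                       snps$ref[i], snps$alt[i], ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF into a dosage matrix
#'
#' @param path VCF path (plain text, GT-only FORMAT).
#' @return List with \code{genotypes} (samples x SNPs dosage matrix) and
#'   \code{snps} (data frame \code{snp, pos, ref, alt}, 0-based
#'   positions).
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  snp <- vapply(fields, `[[`, "", 3)
  pos <- as.integer(vapply(fields, `[[`, "", 2)) - 1L
  ref <- vapply(fields, `[[`, "", 4)
  alt <- vapply(fields, `[[`, "", 5)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  G <- matrix(NA_integer_, length(samples), length(snp),
              dimnames = list(samples, snp))
  for (i in seq_along(fields)) {
    gt <- fields[[i]][-(1:9)]
    G[, i] <- unname(code[gt])
  }
  list(genotypes = G,
       snps = data.frame(snp = snp, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE))
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs))
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  invisible(path)
}

#' Read a FASTA file
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

#' Write PWMs in JASPAR text format
#'
#' Counts are probabilities scaled by 1e6 to preserve precision.
#'
#' @param pwms List of \code{"pwm"} objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in BASES) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(fmt_num(p$mat[b, ] * 1e6),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a JASPAR text PWM file
#'
#' Accepts count or probability matrices; columns are normalized to
#' probabilities.
#'
#' @param path Input path.
#' @return List of \code{"pwm"} objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    meta <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    rows <- lines[hdr[i] + 1:4]
    mat <- t(vapply(rows, function(r) {
      nums <- regmatches(r, gregexpr("[-0-9.eE+]+", r))[[1]]
      as.numeric(nums)
    }, numeric(length(
      regmatches(rows[1], gregexpr("[-0-9.eE+]+", rows[1]))[[1]]))))
    rownames(mat) <- BASES
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[i]] <- pwm(mat, id = meta[1],
                    name = if (length(meta) > 1) meta[2] else meta[1])
  }
  out
}

# ---------------------------------------------------------------------------
# Bundle serialization

#' Write a fixture bundle to a directory
#'
#' Emits every layer in its standard plain-text format: segmentation and
#' peak/TAD/gene BED files, TSV matrices, a minimal VCF, FASTA SNP
#' contexts, a JASPAR PWM file, and TSV/JSON truth tables.
#'
#' @param bundle A \code{"fixture_bundle"}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop("failed writing fixture bundle under '", dir,
         "': cannot create directory", call. = FALSE)
  p <- function(...) file.path(dir, ...)
  ok <- tryCatch({
    cfg <- unclass(bundle$config)
    jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                         digits = NA)

    write_df_tsv(bundle$panel$snps, p("panel_snps.tsv"))
    write_matrix_tsv(bundle$panel$haplotypes, p("panel_haplotypes.tsv"),
                     id_col = "snp")
    write_vcf(bundle$genotypes, bundle$panel$snps, p("genotypes.vcf"),
              contig = bundle$panel$contig)

    dir.create(p("segmentations"), showWarnings = FALSE)
    for (tr in bundle$tracks) {
      nb <- length(tr$states)
      st <- as.character(tr$states)
      # run-length encode into BED4 records
      r <- rle(st)
      ends <- cumsum(r$lengths) * tr$bin_width
      starts <- c(0, ends[-length(ends)])
      write_bed(data.frame(start = starts, end = ends, name = r$values),
                p("segmentations", paste0(tr$sample, ".bed")),
                name_col = "name")
    }

    dir.create(p("layers"), showWarnings = FALSE)
    for (nm in names(bundle$layers)) {
      fm <- bundle$layers[[nm]]
      write_matrix_tsv(fm$values, p("layers", paste0(nm, "_values.tsv")))
      write_matrix_tsv(fm$presence * 1L,
                       p("layers", paste0(nm, "_presence.tsv")))
      write_df_tsv(fm$features, p("layers", paste0(nm, "_features.tsv")))
      write_bed(fm$features, p("layers", paste0(nm, "_features.bed")),
                name_col = "feature_id")
    }
    write_bed(bundle$tads, p("tads.bed"), name_col = "tad")
    write_bed(bundle$genes, p("genes.bed"), name_col = "gene")

    write_df_tsv(bundle$allele_counts, p("allele_counts.tsv"))
    write_df_tsv(bundle$snp_annotations, p("snp_annotations.tsv"))

    write_jaspar(bundle$motif$pwms, p("pwms.jaspar"))
    ctx <- stats::setNames(bundle$motif$snps$context, bundle$motif$snps$snp)
    write_fasta(ctx, p("snp_contexts.fasta"))
    write_df_tsv(bundle$motif$snps, p("motif_snps.tsv"))

    write_df_tsv(bundle$truth$qtl, p("truth_qtl.tsv"))
    write_df_tsv(bundle$truth$imbalanced_snps, p("truth_imbalance.tsv"))
    write_df_tsv(bundle$truth$locus_regions, p("truth_loci.tsv"))
    jsonlite::write_json(
      list(testable_snps = bundle$truth$testable_snps,
           enriched_loci = bundle$truth$enriched_loci,
           active_snp_loci = bundle$truth$active_snp_loci,
           motif_disrupted = bundle$motif$truth),
      p("truth_sets.json"))
    TRUE
  }, error = function(e) {
    stop("failed writing fixture bundle under '", dir, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(dir)
}

#' Read back the core of a written fixture bundle
#'
#' Reconstructs the components written by
#' \code{\link{write_fixture_bundle}}: configuration, panel, genotypes,
#' segmentation tracks, feature layers, TAD/gene maps, allele counts,
#' annotations, motif fixture and truth tables.
#'
#' @param dir Bundle directory.
#' @return A list mirroring the corresponding \code{"fixture_bundle"}
#'   fields.
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  cfg <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)

  snps <- read_df_tsv(p("panel_snps.tsv"))
  hap <- read_matrix_tsv(p("panel_haplotypes.tsv"), id_col = "snp")
  storage.mode(hap) <- "integer"
  vcf <- read_vcf_dosages(p("genotypes.vcf"))
  G <- vcf$genotypes[, snps$snp, drop = FALSE]

  seg_files <- list.files(p("segmentations"), full.names = TRUE)
  tracks <- lapply(seg_files, function(f) {
    bed <- read_bed(f)
    nb <- cfg$genome_length %/% cfg$bin_width
    states <- character(nb)
    for (i in seq_len(nrow(bed))) {
      bins <- (bed$start[i] %/% cfg$bin_width + 1L):
        (bed$end[i] %/% cfg$bin_width)
      states[bins] <- bed$name[i]
    }
    structure(list(sample = sub("\\.bed$", "", basename(f)),
                   bin_width = cfg$bin_width,
                   genome_length = cfg$genome_length,
                   states = factor(states, levels = cfg$state_alphabet)),
              class = "segmentation_track")
  })

  layer_names <- unique(sub("_(values|presence|features)\\.(tsv|bed)$", "",
                            list.files(p("layers"))))
  layers <- stats::setNames(lapply(layer_names, function(nm) {
    V <- read_matrix_tsv(p("layers", paste0(nm, "_values.tsv")))
    P <- read_matrix_tsv(p("layers", paste0(nm, "_presence.tsv"))) > 0
    structure(list(layer = nm, values = V,
                   features = read_df_tsv(p("layers",
                                            paste0(nm, "_features.tsv"))),
                   presence = P),
              class = "feature_matrix")
  }), layer_names)

  tads <- read_bed(p("tads.bed")); names(tads)[4] <- "tad"
  genes <- read_bed(p("genes.bed")); names(genes)[4] <- "gene"

  motif <- list(pwms = read_jaspar(p("pwms.jaspar")),
                snps = read_df_tsv(p("motif_snps.tsv")))
  truth_sets <- jsonlite::read_json(p("truth_sets.json"),
                                    simplifyVector = TRUE)
  list(config = cfg, panel = list(haplotypes = hap, snps = snps),
       genotypes = G, tracks = tracks, layers = layers,
       tads = tads[, c("tad", "start", "end")],
       genes = genes[, c("gene", "start", "end")],
       allele_counts = read_df_tsv(p("allele_counts.tsv")),
       snp_annotations = read_df_tsv(p("snp_annotations.tsv")),
       motif = motif,
       truth = c(list(qtl = read_df_tsv(p("truth_qtl.tsv")),
                      imbalanced_snps = read_df_tsv(p("truth_imbalance.tsv")),
                      locus_regions = read_df_tsv(p("truth_loci.tsv"))),
                 truth_sets))
}
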