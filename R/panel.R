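#' Construct a genotype panel
#'
#' A genotype panel is the central data container of grapekin: a set of
#' individuals typed at diploid, biallelic SNP markers, stored as a dosage
#' matrix counting copies of the B (ALT) allele.
#'
#' @param dosages Integer matrix, individuals in rows and markers in columns.
#'   Permitted values are 0, 1, 2 and `NA` (missing call). Row names are the
#'   individual names, column names the marker ids.
#' @param markers Data frame of marker metadata with columns `marker_id`,
#'   `chrom`, `pos` (1-based), `allele_A`, `allele_B`, one row per column of
#'   `dosages`, in the same order.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages` (the validated matrix) and `markers` (the metadata frame).
#' @examples
#' d <- rbind(s1 = c(0, 1), s2 = c(2, NA))
#' colnames(d) <- c("m1", "m2")
#' m <- data.frame(marker_id = c("m1", "m2"), chrom = "1", pos = c(100, 200),
#'                 allele_A = "A", allele_B = "G")
#' p <- genotype_panel(d, m)
#' @export
genotype_panel <- function(dosages, markers) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  required <- c("marker_id", "chrom", "pos", "allele_A", "allele_B")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols))
    stop("marker metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  markers <- markers[required]
  markers$pos <- as.integer(markers$pos)
  if (nrow(markers) != ncol(dosages))
    stop("marker metadata rows (", nrow(markers),
         ") do not match dosage columns (", ncol(dosages), ")")
  if (is.null(rownames(dosages)))
    stop("dosage matrix must carry individual names as row names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate individual name(s): ",
         paste(unique(rownames(dosages)[duplicated(rownames(dosages))]), collapse = ", "))
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker_id(s): ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]), collapse = ", "))
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- markers$marker_id
  } else if (!identical(colnames(dosages), as.character(markers$marker_id))) {
    stop("dosage column names disagree with marker metadata order")
  }
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad))
    stop("dosages outside {0, 1, 2, NA}: e.g. ", bad[[1]])
  if (any(markers$allele_A == markers$allele_B))
    stop("allele_A equals allele_B for marker(s): ",
         paste(utils::head(markers$marker_id[markers$allele_A == markers$allele_B], 3),
               collapse = ", "))
  if (any(!is.na(markers$pos) & markers$pos < 1L))
    stop("marker positions must be >= 1")
  structure(list(dosages = dosages, markers = markers), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "markers\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  cat("  chromosomes:", length(unique(x$markers$chrom)), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Individual names of a panel
#' @param panel A `genotype_panel`.
#' @return Character vector of individual names.
#' @export
individuals <- function(panel) rownames(panel$dosages)

#' Subset a genotype panel
#'
#' @param x A `genotype_panel`.
#' @param i Individual selector (names, indices or logical).
#' @param j Marker selector (marker ids, indices or logical).
#' @param ... Ignored.
#' @return A `genotype_panel` restricted to the selected individuals/markers.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  d <- x$dosages[i, j, drop = FALSE]
  jj <- match(colnames(d), x$markers$marker_id)
  genotype_panel(d, x$markers[jj, , drop = FALSE])
}

# Map VCF-style GT strings to dosages; half calls and anything unparseable -> NA.
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

#' Read a genotype panel from disk
#'
#' Two formats are supported. `"vcf"` reads diploid, biallelic SNP records
#' (GT field only); multiallelic or non-SNP records are skipped with a
#' message, and half calls become missing. `"dosage"` reads the tabular
#' dialect written by [write_panel()]: a TSV whose first column (`sample`)
#' holds individual names, whose header row holds marker ids and whose cells
#' are 0/1/2/NA, accompanied by a sidecar `<path>.markers.tsv` with columns
#' `marker_id`, `chrom`, `pos`, `allele_A`, `allele_B`.
#'
#' @param path Input file.
#' @param format `"vcf"`, `"dosage"` or `"auto"` (by file extension).
#' @param quiet Suppress the skipped-record message.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path, format = c("auto", "vcf", "dosage"), quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") .read_panel_vcf(path, quiet) else .read_panel_dosage(path)
}

.read_panel_vcf <- function(path, quiet) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0 && !quiet)
    message("read_panel: skipped ", n_skipped, " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (anyDuplicated(colnames(gt)))
    stop("duplicate sample name(s) in VCF: ",
         paste(unique(colnames(gt)[duplicated(colnames(gt))]), collapse = ", "))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  d <- apply(gt, 2, .gt_to_dosage)
  d <- matrix(as.integer(d), nrow = nrow(gt), ncol = ncol(gt),
              dimnames = list(ids, colnames(gt)))
  genotype_panel(t(d),
                 data.frame(marker_id = ids, chrom = fix$CHROM,
                            pos = as.integer(fix$POS),
                            allele_A = fix$REF, allele_B = fix$ALT,
                            stringsAsFactors = FALSE))
}

.read_panel_dosage <- function(path) {
  sidecar <- paste0(path, ".markers.tsv")
  if (!file.exists(sidecar)) stop("missing marker sidecar file: ", sidecar)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample")
    stop("dosage table must start with a 'sample' column (", path, ")")
  if (anyDuplicated(tab$sample))
    stop("duplicate sample name(s) in dosage table: ",
         paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- tab$sample
  mk <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  mk <- mk[match(colnames(d), mk$marker_id), , drop = FALSE]
  if (anyNA(mk$marker_id))
    stop("marker sidecar does not cover all markers in ", path)
  genotype_panel(d, mk)
}

#' Write a genotype panel to disk
#'
#' The inverse of [read_panel()]: `"vcf"` writes an uncompressed VCFv4.2 with
#' a GT-only FORMAT (allele_A as REF, allele_B as ALT, dosage = ALT count);
#' `"dosage"` writes the TSV dialect plus its `<path>.markers.tsv` sidecar.
#' Round-tripping either format reproduces dosages and orderings exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path Output file.
#' @param format `"vcf"`, `"dosage"` or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path)) "vcf" else "dosage"
  if (format == "vcf") .write_panel_vcf(panel, path) else .write_panel_dosage(panel, path)
  invisible(path)
}

.write_panel_vcf <- function(panel, path) {
  d <- panel$dosages
  gt_code <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  idx <- !is.na(t(d))
  body[idx] <- gt_code[t(d)[idx] + 1L]
  mk <- panel$markers
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(d)), collapse = "\t"),
             paste(mk$chrom, mk$pos, mk$marker_id, mk$allele_A, mk$allele_B,
                   ".", "PASS", ".", "GT",
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
}

.write_panel_dosage <- function(panel, path) {
  tab <- data.frame(sample = rownames(panel$dosages),
                    panel$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$markers, paste0(path, ".markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Merge genotype panels on shared markers
#'
#' Panels genotyped on a common array design are merged on the intersection
#' of their `marker_id`s. Allele orientation is reconciled against the first
#' panel: a marker whose (allele_A, allele_B) labels are swapped in a later
#' panel has its dosages flipped d -> 2 - d; a marker whose labels neither
#' match nor swap is dropped and logged. Sample names that collide across
#' panels are suffixed `.2`, `.3`, ... by panel index.
#'
#' @param panels List of two or more [genotype_panel()] objects.
#' @return A merged `genotype_panel`. Attribute `merge_log` records dropped
#'   markers and renamed samples.
#' @export
merge_panels <- function(panels) {
  if (length(panels) < 2) stop("merge_panels needs at least two panels")
  ids <- Reduce(intersect, lapply(panels, function(p) p$markers$marker_id))
  if (length(ids) == 0) stop("panels share no marker_id; empty intersection")
  ref <- panels[[1]]$markers
  ref <- ref[match(ids, ref$marker_id), ]
  dropped <- character(0)
  mats <- vector("list", length(panels))
  renamed <- character(0)
  seen <- character(0)
  keep <- rep(TRUE, length(ids))
  for (k in seq_along(panels)) {
    p <- panels[[k]]
    j <- match(ids, p$markers$marker_id)
    mk <- p$markers[j, ]
    d <- p$dosages[, j, drop = FALSE]
    same <- mk$allele_A == ref$allele_A & mk$allele_B == ref$allele_B
    swap <- mk$allele_A == ref$allele_B & mk$allele_B == ref$allele_A
    if (any(swap)) d[, swap] <- 2L - d[, swap, drop = FALSE]
    bad <- !(same | swap)
    if (any(bad)) {
      dropped <- union(dropped, ids[bad])
      keep <- keep & !bad
    }
    nm <- rownames(d)
    clash <- nm %in% seen
    if (any(clash)) {
      renamed <- c(renamed, nm[clash])
      nm[clash] <- paste0(nm[clash], ".", k)
      rownames(d) <- nm
    }
    seen <- c(seen, nm)
    mats[[k]] <- d
  }
  out <- do.call(rbind, lapply(mats, function(m) m[, keep, drop = FALSE]))
  res <- genotype_panel(out, ref[keep, , drop = FALSE])
  attr(res, "merge_log") <- list(dropped_markers = dropped, renamed_samples = renamed)
  res
}
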