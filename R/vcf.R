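#' Write a dataset as a phased VCF
#'
#' One record per locus (CHROM = locus id, POS = 1) with phased GT fields;
#' REF/ALT are placeholder bases (A/T) since only the 0/1 allele state is
#' meaningful for one-SNP-per-locus data.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param path output file path (plain-text \code{.vcf}).
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(dataset, path) {
  a <- alleleMatrix(dataset)
  nind <- length(sampleIds(dataset))
  gt <- matrix(paste(a[, 2 * seq_len(nind) - 1, drop = FALSE],
                     a[, 2 * seq_len(nind), drop = FALSE], sep = "|"),
               nrow = nrow(a))
  header <- c("##fileformat=VCFv4.2",
              "##source=sfsize",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIds(dataset)), collapse = "\t"))
  body <- cbind(dataset@locusIds, "1", ".", "A", "T", ".", "PASS", ".",
                "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a population map
#'
#' Two-column whitespace/tab-delimited text: sample id, population label.
#' Population order is order of first appearance.
#'
#' @param path file path, or a two-column data.frame passed through.
#' @return data.frame with columns \code{sample}, \code{pop}.
#' @export
readPopMap <- function(path) {
  pm <- if (is.data.frame(path)) path
        else read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(pm) < 2) stop("population map needs two columns: sample, pop")
  pm <- pm[, 1:2]
  names(pm) <- c("sample", "pop")
  if (length(unique(pm$pop)) != 2L)
    stop("population map must define exactly two populations")
  pm
}

#' Read a phased biallelic VCF into a GenotypeDataset
#'
#' Parsing is delegated to \pkg{vcfR}; this layer enforces the data model:
#' biallelic SNPs only, phased GT for every sample at every site, every
#' sample present in the population map.  Sites left monomorphic are
#' dropped (count recorded in provenance).
#'
#' @param path VCF file (plain or gzipped).
#' @param popMap population map file/data.frame, see
#'   \code{\link{readPopMap}}.
#' @return a \linkS4class{GenotypeDataset} with individuals ordered
#'   population 1 first.
#' @export
readVcf <- function(path, popMap) {
  pm <- readPopMap(popMap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- rbind(fix)  # single-record VCF
  if (nrow(fix) == 0L) stop("VCF contains no records")
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    stop("multiallelic or ALT-less records not supported: ",
         paste(fix[multi, "CHROM"][seq_len(min(5, sum(multi)))],
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- rbind(gt)
  samples <- colnames(gt)
  missingMap <- setdiff(samples, pm$sample)
  if (length(missingMap))
    stop("samples absent from population map: ",
         paste(missingMap, collapse = ", "))
  bad <- !grepl("^[01]\\|[01]$", gt)
  dim(bad) <- dim(gt)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    ex <- unique(paste0(fix[idx[, 1], "CHROM"], ":", samples[idx[, 2]],
                        "=", gt[idx]))
    stop("unphased or missing genotypes: ",
         paste(utils::head(ex, 5), collapse = ", "))
  }
  pm <- pm[pm$sample %in% samples, , drop = FALSE]
  pops <- unique(pm$pop)
  ord <- pm$sample[order(match(pm$pop, pops))]
  gt <- gt[, ord, drop = FALSE]
  nind <- length(ord)
  a <- matrix(0L, nrow = nrow(gt), ncol = 2L * nind)
  a[, 2 * seq_len(nind) - 1] <- as.integer(substr(gt, 1, 1))
  a[, 2 * seq_len(nind)] <- as.integer(substr(gt, 3, 3))
  dc <- rowSums(a)
  keep <- dc >= 1L & dc <= ncol(a) - 1L
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("no variable loci in VCF after filtering")
  new("GenotypeDataset",
      alleles = a,
      sampleIds = ord,
      pop = pm$pop[order(match(pm$pop, pops))],
      locusIds = fix[keep, "CHROM"],
      provenance = list(source = if (is.character(path)) path else "vcf",
                        n_records = nrow(gt),
                        n_monomorphic_dropped = sum(!keep)))
}

#' Write a population map for a dataset
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePopMap <- function(dataset, path) {
  write.table(data.frame(sample = sampleIds(dataset),
                         pop = popLabels(dataset)),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(path)
}
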