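#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   subseq reverseComplement translate
NULL

#' Write a PoolSiteTable as a VCF file
#'
#' One multi-sample VCF with per-sample \code{AD} (ref,alt depths) and
#' \code{GQ} fields; pooled samples carry no genotype calls, allele depths are
#' authoritative.
#'
#' @param x A [PoolSiteTable-class].
#' @param path Output path.
#' @param lines Optional subset of line ids to write (default all; pass a
#'   single id for the one-sample-per-file layout).
#' @return \code{path}, invisibly.
#' @export
writeSitesVcf <- function(x, path, lines = NULL) {
  if (is.null(lines)) lines <- lineIds(x)
  j <- match(lines, lineIds(x))
  if (anyNA(j)) stop("unknown line id(s): ", paste(lines[is.na(j)], collapse = ", "))
  rr <- rowRanges(x)
  rd <- refDepth(x)[, j, drop = FALSE]
  ad <- altDepth(x)[, j, drop = FALSE]
  gq <- assay(x, "qual")[, j, drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=poolSweeps",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotyping quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", lines), collapse = "\t"))
  sm <- matrix(paste0(rd, ",", ad, ":", round(gq)), nrow = nrow(x))
  body <- paste(as.character(seqnames(rr)), start(rr), ".",
                rr$ref, rr$alt, ".", "PASS", ".", "AD:GQ",
                apply(sm, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a site table from a VCF, applying the standard pooled-SNP filters
#'
#' Retains biallelic SNPs whose per-sample genotyping quality exceeds
#' \code{minQual} and whose per-sample depth lies in
#' \code{[minDepth, maxDepth]} for every sample, and which do not lie within
#' \code{indelWindow} bp of any indel record (the indel's leftmost reference
#' position; boundary inclusive, so a SNP exactly 10 bp away is dropped and
#' one 11 bp away kept at the defaults). Multi-allelic records are dropped and
#' counted.
#'
#' @param path VCF file with per-sample \code{AD} depths.
#' @param slope Named character vector mapping sample names to
#'   \code{NFS}/\code{SFS}.
#' @param minQual,minDepth,maxDepth,indelWindow Filter thresholds; defaults 30,
#'   10, 250, 10.
#' @return A [PoolSiteTable-class]; the number of dropped multi-allelic
#'   records is attached as \code{metadata(x)$nMultiallelicDropped}.
#' @export
readSites <- function(path, slope, minQual = 30, minDepth = 10,
                      maxDepth = 250, indelWindow = 10) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  isIndel <- !multi & (nchar(ref) > 1L | nchar(alt) > 1L)
  indelPos <- split(pos[isIndel], chrom[isIndel])
  isSnp <- !multi & !isIndel & ref %in% c("A","C","G","T") & alt %in% c("A","C","G","T")
  adStr <- vcfR::extract.gt(v, element = "AD")
  gqStr <- vcfR::extract.gt(v, element = "GQ")
  samples <- colnames(adStr)
  if (!all(samples %in% names(slope)))
    stop("missing slope labels for: ",
         paste(setdiff(samples, names(slope)), collapse = ", "))
  parseAd <- function(col, part) {
    sp <- strsplit(col, ",", fixed = TRUE)
    as.integer(vapply(sp, function(z) if (length(z) >= part) z[part] else NA_character_,
                      character(1)))
  }
  rd <- vapply(seq_along(samples), function(k) parseAd(adStr[, k], 1L),
               integer(nrow(adStr)))
  ad <- vapply(seq_along(samples), function(k) parseAd(adStr[, k], 2L),
               integer(nrow(adStr)))
  gq <- suppressWarnings(matrix(as.numeric(gqStr), nrow = nrow(gqStr)))
  rd <- matrix(rd, ncol = length(samples)); ad <- matrix(ad, ncol = length(samples))
  keep <- isSnp
  depth <- rd + ad
  okDepth <- depth >= minDepth & depth <= maxDepth
  okQual <- is.na(gq) | gq > minQual   # absent GQ treated as passing
  keep <- keep & apply(okDepth, 1L, all) & apply(okQual, 1L, all)
  # indel proximity
  nearIndel <- rep(FALSE, length(pos))
  for (ch in names(indelPos)) {
    ip <- indelPos[[ch]]
    if (!length(ip)) next
    sel <- chrom == ch
    nearIndel[sel] <- vapply(pos[sel], function(p) any(abs(p - ip) <= indelWindow),
                             logical(1))
  }
  keep <- keep & !nearIndel
  keep[is.na(keep)] <- FALSE
  out <- PoolSiteTable(chrom = chrom[keep], pos = pos[keep],
                       ref = ref[keep], alt = alt[keep],
                       refDepth = rd[keep, , drop = FALSE],
                       altDepth = ad[keep, , drop = FALSE],
                       qual = gq[keep, , drop = FALSE],
                       lineId = samples, slope = slope[samples])
  metadata(out)$nMultiallelicDropped <- sum(multi)
  out
}

#' Read gene models from a GFF3 file
#'
#' Parses a gene/mRNA/CDS hierarchy; returns one record per gene (union span
#' over its transcripts) and the CDS intervals tagged with their gene id.
#'
#' @param path GFF3 file.
#' @return List with \code{genes} (\code{GRanges}, \code{gene_id} column) and
#'   \code{cds} (\code{GRanges}, \code{gene_id} column, ordered by position).
#'   Orphan CDS features (no resolvable gene parent) trigger a warning and a
#'   CDS outside its gene span is an error.
#' @export
readGenes <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(g$type)
  genes <- g[typ == "gene"]
  genes$gene_id <- as.character(genes$ID)
  mrna <- g[typ == "mRNA"]
  mrnaParent <- vapply(mrna$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                       character(1))
  cds <- g[typ == "CDS"]
  cdsParent <- vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                      character(1))
  # resolve CDS parent: may be an mRNA or directly a gene
  geneOf <- cdsParent
  viaMrna <- geneOf %in% as.character(mrna$ID)
  geneOf[viaMrna] <- mrnaParent[match(geneOf[viaMrna], as.character(mrna$ID))]
  orphan <- !geneOf %in% genes$gene_id
  if (any(orphan)) {
    warning(sum(orphan), " orphan CDS feature(s) dropped")
    cds <- cds[!orphan]; geneOf <- geneOf[!orphan]
  }
  cds$gene_id <- geneOf
  gi <- match(cds$gene_id, genes$gene_id)
  if (any(start(cds) < start(genes)[gi] | end(cds) > end(genes)[gi]))
    stop("CDS feature outside its gene span")
  keep <- c("gene_id")
  S4Vectors::mcols(genes) <- S4Vectors::mcols(genes)[keep]
  ph <- cds$phase
  S4Vectors::mcols(cds) <- S4Vectors::mcols(cds)["gene_id"]
  cds$phase <- if (is.null(ph)) 0L else as.integer(as.character(ph))
  list(genes = sort(genes, ignore.strand = TRUE),
       cds = sort(cds, ignore.strand = TRUE))
}

#' Write genomic regions as BED
#'
#' BED is 0-based half-open: a 1-based inclusive interval \code{[s, e]} is
#' emitted as \code{(s-1, e)}. Column 4 carries the label.
#'
#' @param regions \code{GRanges}; the label column is taken from
#'   \code{labelCol} when present.
#' @param path Output path.
#' @param labelCol Metadata column used as BED name (default \code{"class"},
#'   falling back to \code{"lineId"}, else \code{"."}).
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path, labelCol = NULL) {
  if (length(regions) && any(end(regions) < start(regions)))
    stop("end < start")
  if (!length(regions)) {
    writeLines("# empty region set", path)
    return(invisible(path))
  }
  regions <- sort(regions, ignore.strand = TRUE)
  mc <- S4Vectors::mcols(regions)
  if (is.null(labelCol))
    labelCol <- intersect(c("class", "lineId"), colnames(mc))[1L]
  lab <- if (!is.na(labelCol) && !is.null(labelCol) && labelCol %in% colnames(mc))
    as.character(mc[[labelCol]]) else rep(".", length(regions))
  writeLines(paste(as.character(seqnames(regions)), start(regions) - 1L,
                   end(regions), lab, sep = "\t"), path)
  invisible(path)
}

#' Read a BED file back into 1-based GRanges
#'
#' Inverse of [writeRegionsBed()]: BED \code{(s0, e)} becomes \code{[s0+1, e]}.
#'
#' @param path BED file.
#' @return \code{GRanges} with a \code{label} column.
#' @export
readRegionsBed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (!length(ln)) {
    out <- GRanges(); out$label <- character(0); return(out)
  }
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  GRanges(f[, 1L], IRanges(as.integer(f[, 2L]) + 1L, as.integer(f[, 3L])),
          label = if (ncol(f) >= 4L) f[, 4L] else ".")
}

#' Write TE insertion records as TSV
#' @param records data.frame with columns family, chrom, pos, line, slope.
#' @param path Output path.
#' @export
writeTeTable <- function(records, path) {
  utils::write.table(records[c("family", "chrom", "pos", "line", "slope")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TE insertion records from TSV
#' @param path TSV with columns family, chrom, pos, line, slope.
#' @export
readTeTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "integer",
                                        "character", "character"))
  d$slope <- .checkSlopes(d$slope)
  d
}

#' Write simulation ground truth as JSON
#' @param truth Ground-truth list from [simulateCohort()].
#' @param path Output path.
#' @export
writeTruth <- function(truth, path) {
  truth$genomeSeed <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write gene models as GFF3
#' @param genes,cds \code{GRanges} as produced by [simulateCohort()].
#' @param path Output path.
#' @export
writeGenesGff3 <- function(genes, cds, path) {
  gl <- paste(as.character(seqnames(genes)), "poolSweeps", "gene",
              start(genes), end(genes), ".", as.character(strand(genes)), ".",
              paste0("ID=", genes$gene_id), sep = "\t")
  ml <- paste(as.character(seqnames(genes)), "poolSweeps", "mRNA",
              start(genes), end(genes), ".", as.character(strand(genes)), ".",
              paste0("ID=", genes$gene_id, ".t1;Parent=", genes$gene_id),
              sep = "\t")
  cl <- paste(as.character(seqnames(cds)), "poolSweeps", "CDS",
              start(cds), end(cds), ".", as.character(strand(cds)),
              if (is.null(cds$phase)) "0" else as.character(cds$phase),
              paste0("ID=", cds$gene_id, ".cds;Parent=", cds$gene_id, ".t1"),
              sep = "\t")
  writeLines(c("##gff-version 3", gl, ml, cl), path)
  invisible(path)
}
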