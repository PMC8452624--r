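#' Genome model: chromosome lengths and centromere positions
#'
#' A genome model is a data frame with one row per chromosome and columns
#' `chrom`, `length` and `centromere` (all bp).  The centromere coordinate
#' splits each chromosome into a p arm (`[0, centromere)`) and a q arm
#' (`[centromere, length)`), which is what the focal/broad classifier and
#' the arm-level frequency tables operate on.
#'
#' The built-in `"hg19"` model carries the standard hg19 chromosome lengths
#' and approximate centromere midpoints for chr1-22, X and Y.
#'
#' @param name model name; only `"hg19"` is built in.
#' @return data frame with columns `chrom`, `length`, `centromere`.
#' @examples
#' gm <- genome_model()
#' gm[gm$chrom == "chr1", ]
#' @export
genome_model <- function(name = "hg19") {
  if (!identical(name, "hg19")) {
    stop("unknown genome model: ", name)
  }
  gm <- data.frame(
    chrom = paste0("chr", c(1:22, "X", "Y")),
    length = c(
      249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566, 155270560, 59373566
    ),
    centromere = c(
      125.0e6, 93.3e6, 91.0e6, 50.4e6, 48.4e6, 61.0e6, 59.9e6, 45.6e6,
      49.0e6, 40.2e6, 53.7e6, 35.8e6, 17.9e6, 17.6e6, 19.0e6, 36.6e6,
      24.0e6, 17.2e6, 26.5e6, 27.5e6, 13.2e6, 14.7e6, 60.6e6, 12.5e6
    ),
    stringsAsFactors = FALSE
  )
  validate_genome_model(gm)
  gm
}

#' Read a genome model from a TSV file
#'
#' Expects a header line and columns `chrom`, `length`, `centromere`.
#'
#' @param path file path.
#' @return genome model data frame.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome model file not found: ", path)
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "length", "centromere")
  if (!all(required %in% names(gm))) {
    stop("genome model must have columns: ", paste(required, collapse = ", "))
  }
  gm$chrom <- normalize_chrom(gm$chrom)
  validate_genome_model(gm)
  gm[required]
}

validate_genome_model <- function(gm) {
  if (anyDuplicated(gm$chrom)) stop("duplicated chromosome in genome model")
  bad <- gm$centromere <= 0 | gm$centromere >= gm$length
  if (any(bad)) {
    stop("centromere outside (0, length) for: ",
         paste(gm$chrom[bad], collapse = ", "))
  }
  invisible(gm)
}

#' Normalize chromosome names to the "chr"-prefixed convention
#'
#' Mixed naming (some names with the `chr` prefix, some without) within one
#' vector is an error: it almost always indicates two files with different
#' conventions being mixed by accident.
#'
#' @param x character vector of chromosome labels.
#' @param prefix logical; `TRUE` (default) returns "chr"-prefixed names,
#'   `FALSE` strips the prefix.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(x, prefix = TRUE) {
  x <- as.character(x)
  if (!length(x)) return(x)
  has <- grepl("^chr", x)
  if (any(has) && !all(has)) {
    stop("mixed chromosome naming (with and without 'chr' prefix)")
  }
  bare <- sub("^chr", "", x)
  if (prefix) paste0("chr", bare) else bare
}

#' Arm membership of a position
#'
#' @param genome genome model.
#' @param chrom chromosome name (normalized internally).
#' @param pos position in bp.
#' @return "p" or "q" for each position.
#' @keywords internal
arm_of <- function(genome, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  ifelse(pos < genome$centromere[i], "p", "q")
}

#' Arm boundaries for one chromosome
#'
#' @return list with `p = c(start, end)` and `q = c(start, end)` in
#'   0-based half-open coordinates.
#' @keywords internal
arm_bounds <- function(genome, chrom) {
  chrom <- normalize_chrom(chrom)
  i <- match(chrom, genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  list(p = c(0, genome$centromere[i]),
       q = c(genome$centromere[i], genome$length[i]))
}

#' Bundled cancer-gene loci (hg19)
#'
#' Coordinates (hg19, 0-based half-open) of the recurrently altered genes
#' tracked by the gene-level CNV caller: PDGFRA, CDK4, CDKN2A, BCOR, NF1,
#' TP53 and MET.
#'
#' @return data frame with columns `symbol`, `chrom`, `start`, `end`.
#' @examples
#' gene_loci()
#' @export
gene_loci <- function() {
  path <- system.file("extdata", "genes_hg19.bed", package = "rigstruct")
  read_gene_bed(path)
}

#' Read gene loci from a BED file
#'
#' BED columns: chrom, start, end, name (0-based half-open, as usual).
#'
#' @param path BED file path.
#' @return data frame with columns `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("gene BED file not found: ", path)
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 4) stop("gene BED needs 4 columns: chrom, start, end, name")
  out <- data.frame(symbol = bed[[4]],
                    chrom = normalize_chrom(bed[[1]]),
                    start = as.numeric(bed[[2]]),
                    end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("invalid gene interval in ", path)
  out
}
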