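#' Karyotype objects
#'
#' A karyotype describes the chromosome complement that the random-breakage
#' model acts on: an ordered set of chromosomes with sizes in megabases, a
#' ploidy (copies per homolog set), and a replication flag (G2/M cells carry
#' two chromatids per chromosome, doubling the DNA content).
#'
#' @param chromosomes data.frame with columns `name` (unique character) and
#'   `size_mb` (strictly positive numeric, megabases).
#' @param ploidy integer number of copies of each homolog set (1 = haploid,
#'   4 = tetraploid).
#' @param replicated logical; `TRUE` for G2/M cells where every chromosome is
#'   present as two sister chromatids.
#' @return An object of class `karyotype`.
#' @examples
#' kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
#' genome_size_mb(kar)
#' @export
karyotype <- function(chromosomes, ploidy = 1L, replicated = FALSE) {
  if (!is.data.frame(chromosomes) ||
      !all(c("name", "size_mb") %in% names(chromosomes))) {
    stop("`chromosomes` must be a data.frame with columns name, size_mb",
         call. = FALSE)
  }
  if (nrow(chromosomes) == 0L) {
    stop("karyotype must contain at least one chromosome", call. = FALSE)
  }
  if (anyDuplicated(chromosomes$name)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (!is.numeric(chromosomes$size_mb) || any(chromosomes$size_mb <= 0)) {
    stop("chromosome sizes must be strictly positive", call. = FALSE)
  }
  stop_scalar(ploidy, "ploidy", positive = TRUE)
  structure(
    list(
      chromosomes = data.frame(
        name = as.character(chromosomes$name),
        size_mb = as.numeric(chromosomes$size_mb),
        stringsAsFactors = FALSE
      ),
      ploidy = as.integer(ploidy),
      replicated = isTRUE(replicated)
    ),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf(
    "karyotype: %d chromosomes, ploidy %d%s, genome %.2f Mb\n",
    nrow(x$chromosomes), x$ploidy,
    if (x$replicated) " (replicated, G2/M)" else "",
    genome_size_mb(x)
  ))
  invisible(x)
}

#' Total genome size in megabases
#'
#' Sum of chromosome sizes times ploidy, doubled for replicated (G2/M)
#' karyotypes. This is the DNA content that multiplies the per-megabase DSB
#' induction efficiency in [expected_dsbs()].
#'
#' @param kar a [karyotype()].
#' @return Numeric, megabases.
#' @export
genome_size_mb <- function(kar) {
  stopifnot(inherits(kar, "karyotype"))
  sum(kar$chromosomes$size_mb) * kar$ploidy * (if (kar$replicated) 2 else 1)
}

#' Number of DNA copies of each chromosome
#'
#' Ploidy times two when replicated: the number of chromatids per chromosome
#' name that contribute to a full-length PFGE band.
#'
#' @param kar a [karyotype()].
#' @return Integer scalar.
#' @export
chromosome_copies <- function(kar) {
  stopifnot(inherits(kar, "karyotype"))
  kar$ploidy * (if (kar$replicated) 2L else 1L)
}

# Standard S. cerevisiae chromosome sizes (kb), rDNA array excluded from
# chromosome XII as in the conventional size table.
.scer_sizes_kb <- function() {
  data.frame(
    name = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrVI", "chrVII",
             "chrVIII", "chrIX", "chrX", "chrXI", "chrXII", "chrXIII",
             "chrXIV", "chrXV", "chrXVI"),
    size_kb = c(230, 813, 317, 1532, 577, 270, 1091, 563, 440, 746, 667,
                1078, 924, 784, 1091, 948),
    stringsAsFactors = FALSE
  )
}

#' Standard budding-yeast karyotype
#'
#' The 16 chromosomes of *Saccharomyces cerevisiae* with conventional sizes
#' (230-1532 kb; 12.07 Mb per haploid set, ribosomal DNA array not counted).
#'
#' @param ploidy copies per homolog set (default 1).
#' @param replicated `TRUE` for G2/M (two chromatids per chromosome).
#' @return A [karyotype()].
#' @examples
#' yeast_karyotype(ploidy = 4, replicated = TRUE)
#' @export
yeast_karyotype <- function(ploidy = 1L, replicated = FALSE) {
  sizes <- .scer_sizes_kb()
  karyotype(
    data.frame(name = sizes$name, size_mb = sizes$size_kb / 1000),
    ploidy = ploidy, replicated = replicated
  )
}

#' Read a karyotype from a two-column TSV
#'
#' Expects a header line and columns `name` and `size_kb`; sizes are
#' converted to megabases.
#'
#' @param path path to a tab-separated file.
#' @inheritParams yeast_karyotype
#' @return A [karyotype()].
#' @export
read_karyotype <- function(path, ploidy = 1L, replicated = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("karyotype file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "size_kb") %in% names(tab))) {
    stop("karyotype file must have columns: name, size_kb", call. = FALSE)
  }
  if (!is.numeric(tab$size_kb)) {
    stop("size_kb column must be numeric", call. = FALSE)
  }
  karyotype(
    data.frame(name = tab$name, size_mb = tab$size_kb / 1000),
    ploidy = ploidy, replicated = replicated
  )
}

#' Write a karyotype to a two-column TSV
#'
#' @param kar a [karyotype()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(kar, path) {
  stopifnot(inherits(kar, "karyotype"))
  utils::write.table(
    data.frame(name = kar$chromosomes$name,
               size_kb = round(kar$chromosomes$size_mb * 1000, 3)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
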