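#' Write a genome to FASTA-like and GFF3-style files
#'
#' The digit sequence goes to a FASTA-like text file (60-column wrapped,
#' header records seed and motifs); the annotation goes to a GFF3-style
#' tab-separated table with 1-based closed intervals and the per-gene
#' attributes `ID`, `n_h`, `cpg_pos` (comma-separated within-gene 0-based
#' positions) and `interactions`
#' (`regulator:sign:weight` triplets, comma-separated). The pair
#' round-trips losslessly through [read_genome()].
#'
#' @param g An `epidrift_genome`.
#' @param fasta,gff Output file paths.
#' @return The input genome, invisibly.
#' @export
write_genome <- function(g, fasta, gff) {
  stopifnot(inherits(g, "epidrift_genome"))
  hdr <- sprintf(">ag seed=%s promoter_motif=%s cpg_motif=%s tf_prefix=%d tf_max_mismatch=%d",
                 format(g$seed), g$promoter_motif, g$cpg_motif,
                 g$tf_prefix, g$tf_max_mismatch)
  n <- nchar(g$sequence)
  starts <- seq(1L, n, by = 60L)
  writeLines(c(hdr, substring(g$sequence, starts, pmin(starts + 59L, n))), fasta)

  ints <- split(g$interactions, g$interactions$target)
  attr_for <- function(i) {
    gi <- g$genes[i, ]
    cp <- paste(gi$cpg_pos[[1]], collapse = ",")
    it <- ints[[as.character(gi$id)]]
    iv <- if (is.null(it)) "" else
      paste(sprintf("%d:%s:%d", it$regulator, it$sign, it$weight), collapse = ",")
    sprintf("ID=gene%d;n_h=%d;cpg_pos=%s;interactions=%s", gi$id, gi$n_h, cp, iv)
  }
  rows <- vapply(seq_len(nrow(g$genes)), function(i) {
    gi <- g$genes[i, ]
    paste("ag", "epidrift", "gene", gi$start + 1L, gi$start + gi$length,
          ".", "+", ".", attr_for(i), sep = "\t")
  }, character(1))
  writeLines(c("##gff-version 3", rows), gff)
  invisible(g)
}

#' Read a genome written by [write_genome()]
#'
#' @param fasta,gff File paths produced by [write_genome()].
#' @return The reconstructed `epidrift_genome`.
#' @export
read_genome <- function(fasta, gff) {
  fl <- readLines(fasta)
  hdr <- fl[[1]]
  kv <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", hdr)
  sequence <- paste(fl[-1], collapse = "")

  gl <- readLines(gff)
  gl <- gl[!startsWith(gl, "#")]
  fields <- strsplit(gl, "\t", fixed = TRUE)
  parse_attr <- function(a, key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", a)
  genes <- purrr::map_dfr(fields, function(f) {
    a <- f[[9]]
    tibble(id = as.integer(sub("gene", "", parse_attr(a, "ID"))),
           start = as.integer(f[[4]]) - 1L,
           length = as.integer(f[[5]]) - as.integer(f[[4]]) + 1L,
           n_h = as.integer(parse_attr(a, "n_h")),
           cpg = parse_attr(a, "cpg_pos"),
           ints = parse_attr(a, "interactions"))
  })
  cpg_pos <- lapply(genes$cpg, function(s)
    if (nzchar(s)) as.integer(strsplit(s, ",")[[1]]) else integer())
  ints <- purrr::map2_dfr(genes$id, genes$ints, function(id, s) {
    if (!nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, ",")[[1]], ":")
    tibble(target = id,
           regulator = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
           sign = vapply(parts, `[[`, character(1), 2),
           weight = vapply(parts, function(p) as.integer(p[[3]]), integer(1)))
  })
  if (!nrow(ints)) {
    ints <- tibble(target = integer(), regulator = integer(),
                   sign = character(), weight = integer())
  }
  seed_str <- kv("seed")
  structure(
    list(sequence = sequence,
         genes = tibble(id = genes$id, start = genes$start,
                        length = genes$length, n_h = genes$n_h,
                        cpg_pos = cpg_pos,
                        n_cpg = vapply(cpg_pos, length, integer(1))),
         interactions = ints,
         seed = if (seed_str == "NA") NA_integer_ else as.integer(seed_str),
         promoter_motif = kv("promoter_motif"), cpg_motif = kv("cpg_motif"),
         tf_prefix = as.integer(kv("tf_prefix")),
         tf_max_mismatch = as.integer(kv("tf_max_mismatch"))),
    class = "epidrift_genome")
}
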