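#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis rbinom rexp runif setNames coef lm var approx
#' @importFrom utils head tail
NULL

# sequence digits as integer vector 0..3
seq_digits <- function(sequence) utf8ToInt(sequence) - utf8ToInt("0")

digits_seq <- function(d) intToUtf8(d + utf8ToInt("0"))

# 0-based start positions of (possibly overlapping) motif occurrences
motif_positions <- function(sequence, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m) - 1L
}

#' Generate an artificial genome
#'
#' Builds a random digit genome (alphabet `0123`) and discovers its genes by
#' scanning for a promoter motif: every motif occurrence opens a gene whose
#' length is drawn uniformly from `gene_length_range` and truncated at the
#' next motif occurrence (and at the sequence end), so gene intervals never
#' overlap. Each gene is annotated with its cooperative nucleosome count
#' `n_h = floor(length / 200)`, its CpG-analog positions and the
#' transcription-factor interaction network (see [annotate_cpgs()] and
#' [build_tf_network()]).
#'
#' Coordinates are 0-based half-open throughout.
#'
#' @param length Genome length in bases.
#' @param seed Integer seed; the same seed reproduces the genome
#'   byte-identically.
#' @param promoter_motif Digit string that opens a gene.
#' @param gene_length_range Two integers, the inclusive range the nominal
#'   gene length is drawn from (before truncation).
#' @param cpg_motif Two-digit string marking a CpG-analog site.
#' @param tf_prefix Length of the gene prefix whose digit complement is the
#'   encoded transcription factor's binding motif.
#' @param tf_max_mismatch Maximum mismatches allowed for a binding site.
#'
#' @return An `epidrift_genome` object: a list with the digit `sequence`,
#'   a `genes` tibble (`id`, `start`, `length`, `n_h`, `n_cpg`, `cpg_pos`
#'   list-column of within-gene 0-based positions), an `interactions`
#'   tibble (`target`, `regulator`, `sign`, `weight`) and the generating
#'   parameters.
#' @examples
#' g <- generate_genome(length = 30000, seed = 1)
#' g$genes
#' @export
generate_genome <- function(length = 120000, seed = 1,
                            promoter_motif = "010101",
                            gene_length_range = c(50, 2000),
                            cpg_motif = "23",
                            tf_prefix = 8, tf_max_mismatch = 1) {
  stopifnot(nchar(promoter_motif) >= 2, nchar(cpg_motif) == 2)
  if (length < 10 * mean(gene_length_range)) {
    stop("genome length must be at least 10x the mean gene length", call. = FALSE)
  }
  set.seed(seed)
  sequence <- digits_seq(sample.int(4L, length, replace = TRUE) - 1L)
  starts <- motif_positions(sequence, promoter_motif)
  if (!base::length(starts)) stop("empty genome: no promoter motif found", call. = FALSE)
  nominal <- sample(seq(gene_length_range[1], gene_length_range[2]),
                    base::length(starts), replace = TRUE)
  gap <- c(diff(starts), length - starts[base::length(starts)])
  glen <- pmin(nominal, gap)
  genes <- tibble(
    id = seq_along(starts),
    start = starts,
    length = as.integer(glen),
    n_h = as.integer(glen %/% 200L)
  )
  g <- structure(
    list(sequence = sequence, genes = genes,
         interactions = tibble(target = integer(), regulator = integer(),
                               sign = character(), weight = integer()),
         seed = as.integer(seed), promoter_motif = promoter_motif, cpg_motif = cpg_motif,
         tf_prefix = tf_prefix, tf_max_mismatch = tf_max_mismatch),
    class = "epidrift_genome")
  g <- annotate_cpgs(g, cpg_motif)
  build_tf_network(g, tf_prefix = tf_prefix, tf_max_mismatch = tf_max_mismatch)
}

#' Annotate CpG-analog sites
#'
#' Rescans every gene's regulatory region (its own interval) for the
#' two-digit CpG motif and records the 0-based within-gene positions.
#' Genes may legitimately carry zero CpGs; short nucleosome-free genes
#' without CpGs form the inert subgroup of the C3 class.
#'
#' @param g An `epidrift_genome`.
#' @param cpg_motif Two-digit string; defaults to the genome's stored motif.
#' @return The genome with refreshed `cpg_pos` and `n_cpg` annotations.
#' @export
annotate_cpgs <- function(g, cpg_motif = g$cpg_motif) {
  stopifnot(inherits(g, "epidrift_genome"), nchar(cpg_motif) == 2)
  regions <- substring(g$sequence, g$genes$start + 1L,
                       g$genes$start + g$genes$length)
  cpg <- lapply(regions, motif_positions, motif = cpg_motif)
  g$genes$cpg_pos <- cpg
  g$genes$n_cpg <- vapply(cpg, base::length, integer(1))
  g$cpg_motif <- cpg_motif
  g
}

# complement transform of a digit vector: 0<->3, 1<->2
digit_complement <- function(d) 3L - d

#' Build the transcription-factor interaction network
#'
#' Every gene encodes a transcription factor whose binding motif is the
#' digit complement of the gene's `tf_prefix`-long sequence prefix. For an
#' ordered pair (regulator j, target i) an interaction is recorded whenever
#' the motif matches a site inside gene i's regulatory region with at most
#' `tf_max_mismatch` mismatches. The digit following a matched site sets
#' its mode (even digit: activating, odd: repressing); the pair's sign is
#' the site majority (ties activate) and its weight the number of matching
#' sites. Genes shorter than `tf_prefix` encode no factor.
#'
#' @param g An `epidrift_genome`.
#' @param tf_prefix,tf_max_mismatch Matching rule; default to the genome's
#'   stored values.
#' @return The genome with a rebuilt `interactions` tibble.
#' @export
build_tf_network <- function(g, tf_prefix = g$tf_prefix,
                             tf_max_mismatch = g$tf_max_mismatch) {
  stopifnot(inherits(g, "epidrift_genome"), tf_prefix >= 2)
  d <- seq_digits(g$sequence)
  genes <- g$genes
  n <- nrow(genes)
  motifs <- vector("list", n)
  for (j in seq_len(n)) {
    if (genes$length[j] >= tf_prefix) {
      motifs[[j]] <- digit_complement(d[genes$start[j] + seq_len(tf_prefix)])
    }
  }
  out <- vector("list", n * 4L)
  k <- 0L
  for (i in seq_len(n)) {
    L <- genes$length[i]
    if (L < tf_prefix) next
    region <- d[genes$start[i] + seq_len(L)]
    n_off <- L - tf_prefix + 1L
    for (j in seq_len(n)) {
      m <- motifs[[j]]
      if (is.null(m)) next
      mis <- integer(n_off)
      for (kk in seq_len(tf_prefix)) {
        mis <- mis + (region[seq_len(n_off) + kk - 1L] != m[kk])
      }
      hits <- which(mis <= tf_max_mismatch)
      if (!base::length(hits)) next
      # digit following each site, taken from the full sequence
      follow_idx <- genes$start[i] + hits - 1L + tf_prefix + 1L
      follow <- d[follow_idx[follow_idx <= base::length(d)]]
      n_act <- sum(follow %% 2L == 0L)
      n_rep <- base::length(follow) - n_act
      k <- k + 1L
      out[[k]] <- tibble(target = genes$id[i], regulator = genes$id[j],
                         sign = if (n_act >= n_rep) "activating" else "repressing",
                         weight = base::length(hits))
    }
  }
  g$interactions <- if (k) dplyr::bind_rows(out[seq_len(k)]) else
    tibble(target = integer(), regulator = integer(),
           sign = character(), weight = integer())
  g$tf_prefix <- tf_prefix
  g$tf_max_mismatch <- tf_max_mismatch
  g
}

#' Construct a deterministic fixture genome
#'
#' Builds a small genome with genes of prescribed lengths and CpG counts,
#' for tests and examples. Gene bodies start with the promoter motif and
#' otherwise use only the digits `2` and `3` (which cannot recreate the
#' promoter), with isolated `2`s placed in a run of `3`s so that each
#' contributes exactly one CpG-analog site `23`.
#'
#' @param lengths Integer vector of gene lengths (back-to-back placement).
#' @param n_cpg Integer vector of CpG counts per gene (capped by the
#'   available body length).
#' @param tail Extra trailing bases after the last gene.
#' @return An `epidrift_genome` with exactly these genes.
#' @examples
#' g <- fixture_genome(lengths = c(150, 800, 1600), n_cpg = c(0, 4, 8))
#' g$genes$n_h
#' @export
fixture_genome <- function(lengths = c(150, 800, 1600),
                           n_cpg = rep(4L, base::length(lengths)),
                           tail = 50L) {
  stopifnot(base::length(lengths) == base::length(n_cpg),
            all(lengths >= 8), all(n_cpg >= 0))
  pm <- "010101"
  bodies <- character(base::length(lengths))
  for (i in seq_along(lengths)) {
    body_len <- lengths[i] - nchar(pm)
    nc <- min(n_cpg[i], body_len %/% 2L)
    body <- rep(3L, body_len)
    if (nc > 0) body[seq_len(nc) * 2L] <- 2L  # isolated 2s -> one "23" each
    bodies[i] <- paste0(pm, digits_seq(body))
  }
  sequence <- paste0(paste(bodies, collapse = ""),
                     digits_seq(rep(3L, tail)))
  genes <- tibble(
    id = seq_along(lengths),
    start = cumsum(c(0L, head(lengths, -1L))),
    length = as.integer(lengths),
    n_h = as.integer(lengths %/% 200L)
  )
  g <- structure(
    list(sequence = sequence, genes = genes,
         interactions = tibble(target = integer(), regulator = integer(),
                               sign = character(), weight = integer()),
         seed = NA_integer_, promoter_motif = pm, cpg_motif = "23",
         tf_prefix = 8, tf_max_mismatch = 1),
    class = "epidrift_genome")
  annotate_cpgs(g)
}

#' @export
print.epidrift_genome <- function(x, ...) {
  cat(sprintf("<epidrift_genome> %d bases, %d genes, %d interactions\n",
              nchar(x$sequence), nrow(x$genes), nrow(x$interactions)))
  cat(sprintf("  n_h range %d..%d; seed %s\n", min(x$genes$n_h),
              max(x$genes$n_h), format(x$seed)))
  invisible(x)
}
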