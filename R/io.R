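#' Read and write study artifacts
#'
#' Plain-text interchange for every intermediate of the pipeline:
#' genotypes as TSV (individuals by markers, dosage -1/0/1, first column
#' `id`), pedigree and phenotype/TBV tables as CSV, marker effects as CSV
#' (with map coordinates when a map is supplied), relationship matrices in
#' a GCTA-GRM-like lower-triangle text format (`i`, `j`, `n_markers`,
#' `value`) with a JSON sidecar holding the scheme, mean IBS and weights,
#' and optionally PLINK `.ped`/`.map` (map positions converted from
#' Morgans to centiMorgans).
#'
#' @param geno Dosage matrix with ids as row names.
#' @param path,prefix Output file path (or path prefix for PLINK).
#' @name tablup-io
NULL

#' @rdname tablup-io
#' @export
write_genotypes <- function(geno, path) {
  df <- as_tibble(geno, .name_repair = \(x) {
    if (all(x == "")) paste0("m", seq_along(x)) else x
  })
  df <- dplyr::bind_cols(tibble(id = rownames(geno)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname tablup-io
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$id)
  m
}

#' @rdname tablup-io
#' @param pop A `gs_population` (pedigree writer and PLINK writer).
#' @export
write_pedigree <- function(pop, path) {
  ped <- if (inherits(pop, "gs_population")) pop$pedigree else pop
  readr::write_csv(ped[, c("id", "sire", "dam", "generation")], path)
  invisible(path)
}

#' @rdname tablup-io
#' @param values Two-column tibble (`id` plus one value column), e.g.
#'   phenotypes or true breeding values.
#' @export
write_values <- function(values, path) {
  readr::write_csv(values, path)
  invisible(path)
}

#' @rdname tablup-io
#' @param trait A `gs_trait`.
#' @export
write_trait <- function(trait, path) {
  readr::write_csv(trait[, c("slot", "chrom", "pos", "effect")], path)
  invisible(path)
}

#' @rdname tablup-io
#' @param effects A `gs_marker_effects`.
#' @param map Optional `gs_map` supplying chromosome/position columns.
#' @export
write_effects <- function(effects, path, map = NULL) {
  out <- tibble(marker = effects$marker, g_hat = effects$g_hat,
                weight = effects$weight)
  if (!is.null(map)) {
    mk <- map$loci[map$loci$type == "marker", ]
    out$chromosome <- mk$chrom
    out$position <- mk$pos
    out <- out[, c("marker", "chromosome", "position", "g_hat", "weight")]
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname tablup-io
#' @param relmat A `gs_relmat`.
#' @export
write_grm <- function(relmat, path) {
  K <- relmat$values
  n <- nrow(K)
  li <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  li <- li[order(li[, 1], li[, 2]), , drop = FALSE]
  readr::write_tsv(tibble(i = li[, 1], j = li[, 2],
                          n_markers = length(relmat$weights),
                          value = K[li]),
                   path, col_names = FALSE)
  meta <- list(scheme = relmat$scheme, s_bar = relmat$s_bar,
               ids = rownames(K), weights = relmat$weights)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname tablup-io
#' @export
read_grm <- function(path) {
  df <- readr::read_tsv(path, col_names = c("i", "j", "n_markers", "value"),
                        show_col_types = FALSE)
  n <- max(df$i)
  K <- matrix(0, n, n)
  K[cbind(df$i, df$j)] <- df$value
  K[cbind(df$j, df$i)] <- df$value
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list(scheme = "unknown", s_bar = NA_real_,
                    weights = rep(NA_real_, df$n_markers[1]))
  if (!is.null(meta$ids)) dimnames(K) <- list(meta$ids, meta$ids)
  structure(list(values = K, scheme = meta$scheme,
                 weights = meta$weights, s_bar = meta$s_bar %||% NA_real_),
            class = "gs_relmat")
}

#' @rdname tablup-io
#' @param generations Generations to export to PLINK (default: all).
#' @export
write_plink <- function(pop, prefix, generations = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  mk <- marker_loci(pop$map)
  mloci <- pop$map$loci[pop$map$loci$type == "marker", ]
  readr::write_tsv(tibble(chrom = mloci$chrom,
                          snp = paste0("m", seq_len(nrow(mloci))),
                          cm = mloci$pos * 100,   # Morgans -> cM
                          bp = seq_len(nrow(mloci))),
                   paste0(prefix, ".map"), col_names = FALSE)
  keep <- if (is.null(generations)) rep(TRUE, nrow(pop$pedigree))
          else pop$pedigree$generation %in% generations
  ped <- pop$pedigree[keep, ]
  h1 <- pop$h1[mk, keep, drop = FALSE]
  h2 <- pop$h2[mk, keep, drop = FALSE]
  lines <- vapply(seq_len(nrow(ped)), function(i) {
    paste(c(1, ped$id[i],
            ifelse(is.na(ped$sire[i]), 0, ped$sire[i]),
            ifelse(is.na(ped$dam[i]), 0, ped$dam[i]),
            ifelse(ped$sex[i] == "M", 1, 2), 0,
            as.vector(rbind(h1[, i], h2[, i]))),
          collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}
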