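# broom-style accessors for the fitted/derived objects.

#' Tidy a pham set
#'
#' One row per gene with its pham assignment.
#'
#' @param x A `pham_set`.
#' @param ... Ignored.
#' @return A tibble (`pham_id`, `gene_id`, `genome_id`).
#' @method tidy pham_set
#' @export
tidy.pham_set <- function(x, ...) x$phams

#' One-row summary of a pham set
#' @param x A `pham_set`.
#' @param ... Ignored.
#' @return A one-row tibble: `n_genes`, `n_phams`, `n_singleton_phams`,
#'   `largest_pham`.
#' @method glance pham_set
#' @export
glance.pham_set <- function(x, ...) {
  tibble(n_genes = nrow(x$phams),
         n_phams = nrow(x$representatives),
         n_singleton_phams = sum(x$representatives$n_members == 1),
         largest_pham = if (nrow(x$representatives))
           max(x$representatives$n_members) else 0L)
}

#' Tidy a neighborhood network
#' @param x A `neighborhood_network`.
#' @param ... Ignored.
#' @return Edge tibble (`pham_a`, `pham_b`, `count`).
#' @method tidy neighborhood_network
#' @export
tidy.neighborhood_network <- function(x, ...) x$edges

#' One-row summary of a neighborhood network
#' @param x A `neighborhood_network`.
#' @param ... Ignored.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_seeds`, `iterations`.
#' @method glance neighborhood_network
#' @export
glance.neighborhood_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_seeds = length(x$seeds), iterations = x$iterations_to_fixpoint)
}

#' Tidy a prophage report
#'
#' One row per prophage call with its status and QC annotations.
#'
#' @param x A `prophage_report`.
#' @param ... Ignored.
#' @return The call tibble without list columns.
#' @method tidy prophage_report
#' @export
tidy.prophage_report <- function(x, ...) {
  x$calls[, setdiff(names(x$calls), c("core", "sequence"))]
}

#' One-row summary of a prophage report
#' @param x A `prophage_report`.
#' @param ... Ignored.
#' @return A one-row tibble of headline counts.
#' @method glance prophage_report
#' @export
glance.prophage_report <- function(x, ...) {
  tibble(n_calls = nrow(x$calls), n_kept = nrow(x$kept),
         n_omitted = nrow(x$omitted),
         n_unique = nrow(x$unique_prophages),
         n_spliced = length(x$spliced),
         n_regions = nrow(x$regions),
         n_attB = if (is.null(x$attB)) 0L else nrow(x$attB),
         n_cassettes = nrow(x$cassettes))
}
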