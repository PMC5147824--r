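#' Read a subcategory-membership table
#'
#' TSV with columns `token` and `subcategories` (comma-separated labels).
#' Every listed token must carry at least one subcategory.
#'
#' @param path Path to the TSV file.
#' @return An object of class `cvf_subcategory_table`: a named list,
#'   token -> character vector of subcategory labels.
#' @export
read_subcategory_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L)
    stop(sprintf("%s: expected columns token, subcategories", path),
         call. = FALSE)
  tok <- normalize_token(as.character(df[[1]]))
  membs <- lapply(strsplit(as.character(df[[2]]), ","), trimws)
  if (any(vapply(membs, function(m) !length(m) || any(!nzchar(m)),
                 logical(1))))
    stop(sprintf("%s: every token needs >= 1 subcategory", path),
         call. = FALSE)
  structure(stats::setNames(membs, tok), class = "cvf_subcategory_table")
}

#' Bundled animal subcategory table
#'
#' The package ships a membership table for the "animals" category based
#' on the 22 non-exclusive subcategories of Troyer et al. (1997): living
#' environment (Africa, Arctic/Far North, Australia, farm, North America,
#' water), human use (beasts of burden, fur, pets), and taxonomy (birds,
#' bovines, canines, deer, felines, fish, insectivores, insects, primates,
#' rabbits, reptiles/amphibians, rodents, weasels).  Following common
#' scoring practice, "tiger" is retained in the African subcategory.
#'
#' @return A `cvf_subcategory_table`.
#' @export
troyer_table <- function() {
  read_subcategory_table(
    system.file("extdata", "troyer_subcategories.tsv",
                package = "cvfluency", mustWork = TRUE))
}

#' Subcategory memberships of a token
#'
#' @param token Character vector of normalized tokens.
#' @param table A `cvf_subcategory_table` (default: [troyer_table()]).
#' @param quiet Suppress the unknown-token warning.
#' @return For one token, a character vector of labels (empty, with a
#'   warning, for unknown tokens); for several, a named list.
#' @examples
#' memberships("rabbit")
#' @export
memberships <- function(token, table = troyer_table(), quiet = FALSE) {
  stopifnot(inherits(table, "cvf_subcategory_table"))
  get1 <- function(tok) {
    m <- table[[tok]]
    if (is.null(m)) {
      if (!quiet)
        warning(sprintf("token '%s' not in subcategory table", tok),
                call. = FALSE)
      character(0)
    } else m
  }
  if (length(token) == 1L) get1(token) else
    stats::setNames(lapply(token, get1), token)
}

#' Subcategory-based (Troyer) switch detection
#'
#' A switch occurs between adjacent words that share no subcategory
#' (pairwise shared-subcategory rule).  Words with no known subcategory
#' produce switches on both sides.  Repetitions are retained in the
#' sequence.
#'
#' @param tokens Character vector of tokens in production order.
#' @param table A `cvf_subcategory_table`.
#' @param quiet Suppress unknown-token warnings.
#' @return Integer vector of switch positions (indices 2..N of tokens that
#'   start a new cluster); zero-length for fewer than two tokens.
#' @examples
#' troyer_switches(c("rabbit", "cat", "tiger", "lion",
#'                   "zebra", "crocodile", "whale"))
#' @export
troyer_switches <- function(tokens, table = troyer_table(), quiet = FALSE) {
  n <- length(tokens)
  if (n < 2L) return(integer(0))
  membs <- lapply(tokens, memberships, table = table, quiet = quiet)
  sw <- vapply(seq_len(n - 1L), function(i)
    length(intersect(membs[[i]], membs[[i + 1L]])) == 0L, logical(1))
  which(sw) + 1L
}

#' Subcategory-based switch and cluster summary
#'
#' @inheritParams troyer_switches
#' @return A list of class `cvf_troyer_summary`: `n_switches`,
#'   `switch_positions`, `n_multiword_clusters`,
#'   `mean_multiword_cluster_size` (sizes counted in words),
#'   `cluster_sizes`.
#' @export
troyer_summary <- function(tokens, table = troyer_table(), quiet = FALSE) {
  sw <- troyer_switches(tokens, table, quiet)
  cs <- cluster_stats(length(tokens), sw)
  structure(list(
    n_switches = length(sw),
    switch_positions = sw,
    n_multiword_clusters = cs$n_multiword_clusters,
    mean_multiword_cluster_size = cs$mean_multiword_cluster_size,
    cluster_sizes = cs$cluster_sizes
  ), class = "cvf_troyer_summary")
}
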