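#' Build the spatial association graph of a session
#'
#' Two sightings are associated when their Euclidean distance is at most
#' `radius` metres (boundary inclusive) and the open segment between them
#' crosses no sight-blocking barrier. Touching a barrier endpoint does
#' not block.
#'
#' @param positions two-column matrix/data frame of x/y coordinates
#'   (metres).
#' @param barriers data frame `x1,y1,x2,y2` or NULL.
#' @param radius association radius in metres (default 5).
#' @return integer matrix with columns `i`, `j` (i < j), zero rows when
#'   there are no edges.
#' @export
build_association_graph <- function(positions, barriers = NULL, radius = 5) {
  if (radius <= 0) stop("radius must be > 0")
  pos <- as.matrix(positions)[, 1:2, drop = FALSE]
  storage.mode(pos) <- "double"
  if (!all(is.finite(pos))) stop("positions must be finite")
  n <- nrow(pos)
  if (n < 2L) return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  d <- as.matrix(stats::dist(pos))
  cand <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  if (nrow(cand) && !is.null(barriers) && nrow(barriers)) {
    ok <- vapply(seq_len(nrow(cand)), function(r) {
      has_line_of_sight(pos[cand[r, 1], ], pos[cand[r, 2], ], barriers)
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
  }
  colnames(cand) <- c("i", "j")
  cand
}

#' Connected components of an association graph
#'
#' Subgroups are the transitive closure of the pairwise association:
#' chains count as one subgroup even when distant members exceed the
#' radius pairwise. Isolated birds form subgroups of size one.
#'
#' @param edges two-column edge matrix from [build_association_graph()].
#' @param n_points number of sightings in the session.
#' @return integer component labels (1..n_components) per point.
#' @export
connected_components <- function(edges, n_points) {
  n_points <- as.integer(n_points)
  if (n_points < 1L) return(integer(0))
  g <- igraph::make_empty_graph(n = n_points, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges[, 1:2, drop = FALSE]))
  }
  as.integer(igraph::components(g)$membership)
}

#' Per-session subgroup table
#'
#' Excludes flying birds, computes subgroups per session under the
#' radius/line-of-sight chain rule, and returns one row per nonflying
#' sighting carrying its subgroup's size (size-biased by construction,
#' matching per-observation count models) together with the session
#' covariates, zone attributes and the number of crows recorded in the
#' session.
#'
#' @param records sightings data frame (needs `date`, `session`, `x_m`,
#'   `y_m`, `flying`; covariate/zone columns are carried through when
#'   present).
#' @param world a `crow_world` (for barriers); NULL means no barriers.
#' @param radius association radius in metres.
#' @return data frame of class `subgroup_table`: per-record rows with
#'   `subgroup_id` (unique across sessions), `subgroup_size`,
#'   `n_crows_present`, plus carried columns; attribute `subgroups`: one
#'   row per subgroup (`date`, `session`, `subgroup_id`, `size`).
#' @export
subgroup_table <- function(records, world = NULL, radius = 5) {
  stopifnot(all(c("date", "session", "x_m", "y_m", "flying") %in% names(records)))
  barriers <- if (!is.null(world)) world$barriers else NULL
  bad <- !is.finite(records$x_m) | !is.finite(records$y_m)
  if (any(bad & records$flying == 0L)) {
    warning(sum(bad & records$flying == 0L),
            " nonflying record(s) without position excluded")
  }
  nf <- records[records$flying == 0L & !bad, , drop = FALSE]
  if (nrow(nf) == 0L) {
    out <- nf
    out$subgroup_id <- integer(0)
    out$subgroup_size <- integer(0)
    out$n_crows_present <- integer(0)
    attr(out, "subgroups") <- data.frame(date = as.Date(character()),
                                         session = character(),
                                         subgroup_id = integer(),
                                         size = integer())
    class(out) <- c("subgroup_table", class(out))
    return(out)
  }
  nf$date <- as.Date(nf$date)
  skey <- paste(nf$date, nf$session)
  # crows present per session counts every record, flying included
  all_key <- paste(as.Date(records$date), records$session)
  n_present <- table(all_key)
  parts <- split(seq_len(nrow(nf)), skey)
  next_id <- 0L
  nf$subgroup_id <- NA_integer_
  nf$subgroup_size <- NA_integer_
  glist <- list()
  for (kk in names(parts)) {
    rows <- parts[[kk]]
    pos <- cbind(nf$x_m[rows], nf$y_m[rows])
    comp <- connected_components(
      build_association_graph(pos, barriers, radius), length(rows))
    sizes <- tabulate(comp)
    nf$subgroup_id[rows] <- next_id + comp
    nf$subgroup_size[rows] <- sizes[comp]
    glist[[kk]] <- data.frame(date = nf$date[rows[1]],
                              session = nf$session[rows[1]],
                              subgroup_id = next_id + seq_along(sizes),
                              size = sizes)
    next_id <- next_id + length(sizes)
  }
  nf$n_crows_present <- as.integer(n_present[skey])
  attr(nf, "subgroups") <- do.call(rbind, unname(glist))
  class(nf) <- c("subgroup_table", class(nf))
  nf
}

#' @export
print.subgroup_table <- function(x, ...) {
  g <- attr(x, "subgroups")
  cat("<subgroup_table> ", nrow(x), " nonflying sightings in ",
      nrow(g), " subgroups\n", sep = "")
  cat(sprintf("  mean subgroup size %.2f (per subgroup), %.2f (per record)\n",
              mean(g$size), mean(x$subgroup_size)))
  invisible(x)
}
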