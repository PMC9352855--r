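# Directed model structures: sets of contemporaneous (lag 0) and lagged
# (lag 1) paths among ROIs, at the autoregressive, group, or individual
# level. A path source -> target with lag 0 means the target is regressed
# on the source at the same time point; lag 1 means on the source at the
# previous time point. Lag-1 self-paths are the autoregressive (AR) paths.

#' Create a directed uSEM network structure
#'
#' @param paths `NULL` or a data frame with columns `source`, `target`,
#'   `lag` (0 or 1) and optionally `level` (one of `"ar"`, `"group"`,
#'   `"individual"`; defaults to `"group"` for non-AR paths).
#' @param rois An [roi_set()] or character vector of ROI labels.
#' @param include_ar If `TRUE` (default), every ROI's lag-1 self-path is
#'   added automatically at level `"ar"`.
#'
#' @return An object of class `network_structure`.
#' @export
network_structure <- function(paths = NULL, rois, include_ar = TRUE) {
  labels <- roi_labels(rois)
  if (is.null(paths)) {
    paths <- data.frame(
      source = character(), target = character(),
      lag = integer(), level = character(), stringsAsFactors = FALSE
    )
  }
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "lag") %in% names(paths))) {
    input_error("paths must have columns source, target, lag")
  }
  if (is.null(paths$level)) {
    paths$level <- ifelse(paths$source == paths$target & paths$lag == 1L, "ar", "group")
  }
  paths <- paths[, c("source", "target", "lag", "level")]
  paths$source <- as.character(paths$source)
  paths$target <- as.character(paths$target)
  paths$lag <- as.integer(paths$lag)
  paths$level <- as.character(paths$level)

  bad <- !(paths$source %in% labels) | !(paths$target %in% labels)
  if (any(bad)) {
    input_error(sprintf(
      "unknown ROI label(s) in paths: %s",
      paste(unique(c(paths$source[bad], paths$target[bad])), collapse = ", ")
    ))
  }
  if (!all(paths$lag %in% c(0L, 1L))) input_error("path lag must be 0 or 1")
  if (!all(paths$level %in% c("ar", "group", "individual"))) {
    input_error("path level must be 'ar', 'group' or 'individual'")
  }
  if (any(paths$source == paths$target & paths$lag == 0L)) {
    input_error("contemporaneous self-paths are not allowed")
  }
  if (include_ar) {
    have <- paths$source == paths$target & paths$lag == 1L
    missing_ar <- setdiff(labels, paths$source[have])
    if (length(missing_ar)) {
      paths <- rbind(paths, data.frame(
        source = missing_ar, target = missing_ar, lag = 1L, level = "ar",
        stringsAsFactors = FALSE
      ))
    }
    paths$level[paths$source == paths$target & paths$lag == 1L] <- "ar"
  }
  if (anyDuplicated(path_key(paths))) input_error("duplicate paths in structure")
  rownames(paths) <- NULL
  structure(
    list(paths = sort_paths(paths, labels), labels = labels, include_ar = include_ar),
    class = "network_structure"
  )
}

#' Null structure: autoregressive paths only
#'
#' The search's starting model — no cross-ROI connections, only the lag-1
#' self-path of every ROI (when `include_ar = TRUE`).
#'
#' @inheritParams network_structure
#' @return A `network_structure`.
#' @export
null_structure <- function(rois, include_ar = TRUE) {
  network_structure(NULL, rois, include_ar = include_ar)
}

path_key <- function(paths) {
  sprintf("%d:%s>%s", paths$lag, paths$source, paths$target)
}

sort_paths <- function(paths, labels) {
  si <- match(paths$source, labels)
  ti <- match(paths$target, labels)
  lv <- match(paths$level, c("ar", "group", "individual"))
  paths[order(lv, paths$lag, si, ti), , drop = FALSE]
}

st_add_path <- function(structure, source, target, lag, level) {
  new <- rbind(structure$paths, data.frame(
    source = source, target = target, lag = as.integer(lag), level = level,
    stringsAsFactors = FALSE
  ))
  network_structure(new, structure$labels, include_ar = structure$include_ar)
}

st_drop_keys <- function(structure, keys) {
  keep <- !(path_key(structure$paths) %in% keys)
  network_structure(structure$paths[keep, , drop = FALSE], structure$labels,
    include_ar = structure$include_ar
  )
}

st_has <- function(structure, key) key %in% path_key(structure$paths)

n_paths <- function(structure) nrow(structure$paths)

# Adjacency of the contemporaneous (lag 0) subgraph; adj[s, t] = TRUE for
# a path s -> t.
lag0_adjacency <- function(structure) {
  p <- length(structure$labels)
  adj <- matrix(FALSE, p, p, dimnames = list(structure$labels, structure$labels))
  c0 <- structure$paths[structure$paths$lag == 0L, , drop = FALSE]
  if (nrow(c0)) adj[cbind(match(c0$source, structure$labels), match(c0$target, structure$labels))] <- TRUE
  adj
}

# Transitive closure: reach[i, j] = TRUE if a directed lag-0 walk i ~> j exists.
lag0_reachability <- function(structure) {
  adj <- lag0_adjacency(structure)
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

has_lag0_cycle <- function(structure) {
  any(diag(lag0_reachability(structure)))
}

# All admissible absent paths: every ordered pair at lag 0 (no self) and
# lag 1 (self allowed when AR not already present), minus existing paths.
candidate_paths <- function(structure) {
  labels <- structure$labels
  grid <- expand.grid(
    source = labels, target = labels, lag = c(0L, 1L),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[!(grid$source == grid$target & grid$lag == 0L), , drop = FALSE]
  grid <- grid[!(sprintf("%d:%s>%s", grid$lag, grid$source, grid$target) %in%
    path_key(structure$paths)), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' @export
print.network_structure <- function(x, ...) {
  tab <- table(factor(x$paths$level, levels = c("ar", "group", "individual")))
  cat(sprintf(
    "uSEM structure on %d ROIs: %d paths (%d AR, %d group, %d individual)\n",
    length(x$labels), nrow(x$paths), tab[["ar"]], tab[["group"]], tab[["individual"]]
  ))
  nonar <- x$paths[x$paths$level != "ar", , drop = FALSE]
  if (nrow(nonar)) {
    lab <- sprintf(
      "  %s %s %s [%s, %s]", nonar$source,
      ifelse(nonar$lag == 0L, "->", "=>"), nonar$target,
      ifelse(nonar$lag == 0L, "lag 0", "lag 1"), nonar$level
    )
    cat(lab, sep = "\n")
  }
  invisible(x)
}
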