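#' Remove low-confidence scaffold placements
#'
#' A scaffold is dropped when its markers all come from a single linkage
#' map, that map derives from a single-queen family, and the scaffold has
#' fewer than four markers in it. Scaffolds supported by several maps, by
#' a multiple-queen family, or by four or more markers are kept.
#'
#' @param markers Marker data.frame (see [read_markers()]).
#' @param min_markers Marker-count threshold (default 4; scaffolds with
#'   fewer are removed under the single single-queen-map condition).
#' @return The filtered marker data.frame.
#' @export
filter_low_confidence_scaffolds <- function(markers, min_markers = 4) {
  drop <- vapply(split(markers, markers$scaffold), function(m) {
    fams <- unique(m$family_id)
    length(fams) == 1L &&
      all(m$family_type == "single-queen") &&
      nrow(m) < min_markers
  }, logical(1))
  markers[!markers$scaffold %in% names(drop)[drop], , drop = FALSE]
}

#' Split scaffolds with markers in several linkage groups
#'
#' Scaffolds whose markers map to two or more linkage groups are treated
#' as assembly chimeras: each linkage group's markers define one retained
#' segment spanning their positional range, and sequence outside all
#' segments is dropped from the map. Interleaved per-group ranges cannot
#' be resolved and raise an error.
#'
#' @param markers Marker data.frame.
#' @return List with `markers` (unchanged rows, all retained) and
#'   `segments`: data.frame `scaffold`, `linkage_group`, `seg_start`,
#'   `seg_end` for every chimeric scaffold.
#' @export
split_chimeric_scaffolds <- function(markers) {
  segs <- list()
  for (sc in unique(markers$scaffold)) {
    m <- markers[markers$scaffold == sc, ]
    lgs <- unique(m$linkage_group)
    if (length(lgs) < 2L) next
    rng <- do.call(rbind, lapply(lgs, function(lg) {
      p <- m$pos[m$linkage_group == lg]
      data.frame(scaffold = sc, linkage_group = lg,
                 seg_start = min(p), seg_end = max(p))
    }))
    rng <- rng[order(rng$seg_start), ]
    if (any(rng$seg_start[-1] <= rng$seg_end[-nrow(rng)]))
      stop("irresolvable chimera: overlapping linkage-group marker ranges ",
           "on scaffold ", sc)
    segs[[sc]] <- rng
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(scaffold = character(), linkage_group = character(),
               seg_start = integer(), seg_end = integer())
  rownames(segments) <- NULL
  list(markers = markers, segments = segments)
}

#' Place scaffold segments on pseudo-chromosomes
#'
#' Orders segments within each linkage group by mean marker cM position
#' and orients them by the sign of the cM-vs-bp correlation of their
#' markers (`"+"` increasing, `"-"` decreasing, `"unknown"` for single
#' markers or ties). Pseudo-chromosome coordinates are the cumulative bp
#' offsets of the ordered segments.
#'
#' @param markers Marker data.frame (ideally filtered and split first).
#' @param scaffold_lengths Named vector of scaffold lengths; non-chimeric
#'   scaffolds are placed whole, chimeric segments only over their marker
#'   ranges.
#' @return data.frame of class `genome_map`: `linkage_group`, `scaffold`,
#'   `seg_start`, `seg_end`, `order`, `orientation`, `pseudo_start`,
#'   `pseudo_end`.
#' @export
build_map <- function(markers, scaffold_lengths) {
  split_res <- split_chimeric_scaffolds(markers)
  segments <- split_res$segments
  chimeric <- unique(segments$scaffold)
  rows <- list()
  for (sc in unique(markers$scaffold)) {
    m <- markers[markers$scaffold == sc, ]
    if (sc %in% chimeric) {
      sg <- segments[segments$scaffold == sc, ]
      for (i in seq_len(nrow(sg))) {
        mi <- m[m$linkage_group == sg$linkage_group[i] &
                  m$pos >= sg$seg_start[i] & m$pos <= sg$seg_end[i], ]
        rows[[length(rows) + 1L]] <-
          segment_row(sc, sg$linkage_group[i], sg$seg_start[i],
                      sg$seg_end[i], mi)
      }
    } else {
      len <- scaffold_lengths[[sc]]
      if (is.null(len) || is.na(len))
        stop("scaffold length unknown for ", sc)
      rows[[length(rows) + 1L]] <-
        segment_row(sc, m$linkage_group[1], 1L, len, m)
    }
  }
  map <- do.call(rbind, rows)
  map <- map[order(map$linkage_group, map$mean_cm, map$scaffold), ]
  map$order <- stats::ave(seq_len(nrow(map)), map$linkage_group,
                          FUN = seq_along)
  lens <- map$seg_end - map$seg_start + 1L
  offset <- stats::ave(lens, map$linkage_group,
                       FUN = function(x) cumsum(x) - x)
  map$pseudo_start <- offset + 1L
  map$pseudo_end <- offset + lens
  map$mean_cm <- NULL
  rownames(map) <- NULL
  class(map) <- c("genome_map", "data.frame")
  map
}

segment_row <- function(sc, lg, start, end, m) {
  ori <- "unknown"
  if (nrow(m) >= 2 && stats::sd(m$pos) > 0 && stats::sd(m$cM) > 0) {
    r <- stats::cor(m$pos, m$cM)
    if (!is.na(r) && r > 0) ori <- "+"
    if (!is.na(r) && r < 0) ori <- "-"
  }
  data.frame(linkage_group = lg, scaffold = sc,
             seg_start = as.integer(start), seg_end = as.integer(end),
             orientation = ori, mean_cm = mean(m$cM),
             stringsAsFactors = FALSE)
}

#' Scaffolds anchored to a diagnostic locus
#'
#' Returns the scaffolds containing at least one marker flagged as
#' cosegregating with the anchor locus (the Gp-9 marker of the supergene
#' region in the motivating system).
#'
#' @param markers Marker data.frame with a 0/1 `cosegregates_gp9` column
#'   (or the column named by `flag`).
#' @param flag Name of the flag column.
#' @return Character vector of scaffold ids.
#' @export
anchor_markers <- function(markers, flag = "cosegregates_gp9") {
  if (!flag %in% names(markers)) return(character(0))
  sort(unique(markers$scaffold[markers[[flag]] %in% c(1, TRUE)]))
}

#' Convert scaffold coordinates to pseudo-chromosome coordinates
#'
#' The single place where scaffold-local 1-based positions are translated
#' into cumulative linkage-group coordinates; positions falling outside
#' every placed segment return NA.
#'
#' @param map A `genome_map` from [build_map()].
#' @param scaffold,pos Vectors of scaffold ids and 1-based positions.
#' @return data.frame with `linkage_group` and `pseudo_pos` (orientation
#'   "-" segments are reversed within their span).
#' @export
scaffold_to_pseudo <- function(map, scaffold, pos) {
  lg <- rep(NA_character_, length(pos))
  pp <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(map))) {
    hit <- scaffold == map$scaffold[i] &
      pos >= map$seg_start[i] & pos <= map$seg_end[i]
    if (!any(hit)) next
    local <- pos[hit] - map$seg_start[i]
    if (map$orientation[i] == "-")
      local <- (map$seg_end[i] - map$seg_start[i]) - local
    lg[hit] <- map$linkage_group[i]
    pp[hit] <- map$pseudo_start[i] + local
  }
  data.frame(linkage_group = lg, pseudo_pos = pp)
}
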