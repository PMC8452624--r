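#' Parameters for eccDNA structure reconstruction
#'
#' @param amp_threshold minimal mean log2 ratio for a segment to count as
#'   highly amplified (default 2.0, roughly > 8 copies on diploid).
#' @param tolerance_bp maximal distance between an SV breakend and a
#'   segment boundary for the join to be accepted as an amplicon edge
#'   (segmentation and breakpoint calls differ in resolution).
#' @param max_segments exhaustive-search cap on the number of amplified
#'   segments per chromosome set; larger graphs raise an error suggesting
#'   a higher amplification threshold.
#' @return parameter list.
#' @export
eccdna_params <- function(amp_threshold = 2.0, tolerance_bp = 10000,
                          max_segments = 20) {
  stopifnot(tolerance_bp >= 0, max_segments >= 1, max_segments <= 50)
  list(amp_threshold = amp_threshold, tolerance_bp = tolerance_bp,
       max_segments = max_segments)
}

#' Select highly amplified segments as amplicon-graph nodes
#'
#' @param segments segment data frame.
#' @param amp_threshold minimal seg_mean (inclusive).
#' @return the amplified segments with a `node` id column (ordered by
#'   chromosome and start).
#' @export
select_amplified_segments <- function(segments, amp_threshold = 2.0) {
  amp <- segments[segments$seg_mean >= amp_threshold, , drop = FALSE]
  amp <- amp[order(amp$chrom, amp$start), , drop = FALSE]
  if (nrow(amp)) amp$node <- seq_len(nrow(amp)) else amp$node <- integer()
  rownames(amp) <- NULL
  amp
}

#' Build the amplicon graph from amplified segments and SV joins
#'
#' Every node (amplified segment) has a left end (its start) and a right
#' end (its end).  A join becomes an edge when each of its breakends lies
#' within `tolerance_bp` of a matching boundary of some node: a `+` strand
#' breakend attaches to a right end, a `-` strand breakend to a left end
#' (the strand encodes which side of the junction the retained sequence
#' lies on).  Among candidate boundaries the nearest wins; an exact
#' distance tie goes to the lower-coordinate boundary with a warning.
#' Joins with any unmatched breakend are reported, not dropped silently.
#'
#' @param nodes amplified segments from [select_amplified_segments()].
#' @param joins SV joins data frame (see [read_bedpe()]).
#' @param tolerance_bp boundary matching tolerance.
#' @return object of class `amplicon_graph`: list with `nodes`, `edges`
#'   (data frame: `node1`, `end1`, `node2`, `end2`, `join_row`) and
#'   `unmatched` (row indices of joins without an edge).
#' @export
build_amplicon_graph <- function(nodes, joins, tolerance_bp = 10000) {
  stopifnot(tolerance_bp >= 0)
  match_end <- function(chrom, pos, strand) {
    if (strand == "+") {
      cand <- which(nodes$chrom == chrom)
      bound <- nodes$end[cand]; end_lab <- "R"
    } else {
      cand <- which(nodes$chrom == chrom)
      bound <- nodes$start[cand]; end_lab <- "L"
    }
    if (!length(cand)) return(NULL)
    d <- abs(bound - pos)
    ok <- d <= tolerance_bp
    if (!any(ok)) return(NULL)
    cand <- cand[ok]; bound <- bound[ok]; d <- d[ok]
    best <- which(d == min(d))
    if (length(best) > 1) {
      warning("ambiguous breakend at ", chrom, ":", pos,
              "; attached to lower-coordinate boundary")
      best <- best[which.min(bound[best])]
    }
    list(node = nodes$node[cand[best]], end = end_lab)
  }
  edges <- list(); unmatched <- integer()
  for (r in seq_len(nrow(joins))) {
    a <- match_end(joins$chrom1[r], joins$pos1[r], joins$strand1[r])
    b <- match_end(joins$chrom2[r], joins$pos2[r], joins$strand2[r])
    if (is.null(a) || is.null(b)) {
      unmatched <- c(unmatched, r)
    } else {
      edges[[length(edges) + 1]] <- data.frame(
        node1 = a$node, end1 = a$end, node2 = b$node, end2 = b$end,
        join_row = r, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node1 = integer(), end1 = character(), node2 = integer(),
               end2 = character(), join_row = integer(),
               stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, unmatched = unmatched),
            class = "amplicon_graph")
}

#' @export
print.amplicon_graph <- function(x, ...) {
  cat(sprintf("Amplicon graph: %d amplified segments, %d edges, %d unmatched joins\n",
              nrow(x$nodes), nrow(x$edges), length(x$unmatched)))
  invisible(x)
}

#' Enumerate eccDNA candidate cycles in an amplicon graph
#'
#' Exhaustive depth-first enumeration of all simple cycles in which every
#' segment is traversed through (entered at one end, exited at the other).
#' An edge incident to a node's left end continues rightwards through the
#' segment (orientation `+`); incident to the right end, leftwards (`-`).
#' Cycles are deduplicated under rotation and reversal by anchoring each
#' cycle at its smallest node id in `+` orientation, and sorted by total
#' amplified mass (sum of length x 2^seg_mean) in decreasing order.
#'
#' @param graph `amplicon_graph` from [build_amplicon_graph()].
#' @param max_segments node cap for the exhaustive search.
#' @return list of `ecc_cycle` objects (fields `nodes`, `orientations`,
#'   `segments`, `joins`, `total_length`, `n_segments`, `mass`).
#' @export
find_cycles <- function(graph, max_segments = 20) {
  nodes <- graph$nodes
  if (nrow(nodes) > max_segments) {
    stop("amplicon graph has ", nrow(nodes), " nodes (cap ", max_segments,
         "); raise the amplification threshold")
  }
  edges <- graph$edges
  if (!nrow(edges)) return(list())
  # adjacency between ports; each edge usable in both directions
  port <- function(node, end) paste0(node, ".", end)
  adj <- list()
  add <- function(p, node, end, e) {
    adj[[p]] <<- rbind(adj[[p]],
                       data.frame(node = node, end = end, edge = e))
  }
  for (e in seq_len(nrow(edges))) {
    add(port(edges$node1[e], edges$end1[e]), edges$node2[e], edges$end2[e], e)
    add(port(edges$node2[e], edges$end2[e]), edges$node1[e], edges$end1[e], e)
  }
  other_end <- function(end) if (end == "L") "R" else "L"
  cycles <- list()
  emit <- function(path_nodes, path_orient, path_edges) {
    cycles[[length(cycles) + 1]] <<- list(nodes = path_nodes,
                                          orientations = path_orient,
                                          edges = path_edges)
  }
  dfs <- function(start, cur_node, cur_exit_end, path_nodes, path_orient,
                  path_edges, used_edges) {
    out <- adj[[port(cur_node, cur_exit_end)]]
    if (is.null(out)) return()
    for (k in seq_len(nrow(out))) {
      nxt <- out$node[k]; entry <- out$end[k]; e <- out$edge[k]
      if (e %in% used_edges) next
      if (nxt == start && entry == "L") {
        emit(path_nodes, path_orient, c(path_edges, e))
        next
      }
      if (nxt %in% path_nodes || nxt < start) next
      orient <- if (entry == "L") "+" else "-"
      dfs(start, nxt, other_end(entry), c(path_nodes, nxt),
          c(path_orient, orient), c(path_edges, e), c(used_edges, e))
    }
  }
  for (s in nodes$node) {
    # anchor: cycle starts at its minimal node, traversed L -> R ("+")
    dfs(s, s, "R", s, "+", integer(), integer())
  }
  # collapse parallel-edge duplicates and any residual symmetric duplicates
  key <- vapply(cycles, function(cy)
    paste(paste(cy$nodes, cy$orientations, collapse = ";"),
          length(cy$edges)), "")
  cycles <- cycles[!duplicated(key)]
  out <- lapply(cycles, function(cy) {
    segs <- nodes[match(cy$nodes, nodes$node), , drop = FALSE]
    structure(list(nodes = cy$nodes, orientations = cy$orientations,
                   segments = segs,
                   joins = edges$join_row[cy$edges],
                   total_length = sum(segs$end - segs$start),
                   n_segments = length(cy$nodes),
                   mass = sum((segs$end - segs$start) * 2^segs$seg_mean)),
              class = "ecc_cycle")
  })
  out[order(vapply(out, `[[`, 0, "mass"), decreasing = TRUE)]
}

#' @export
print.ecc_cycle <- function(x, ...) {
  lab <- paste0(x$segments$chrom, ":",
                format(x$segments$start, scientific = FALSE, trim = TRUE), "-",
                format(x$segments$end, scientific = FALSE, trim = TRUE),
                "(", x$orientations, ")")
  cat("eccDNA cycle:", paste(lab, collapse = " -> "), "-> back\n")
  cat(sprintf("  %d segments, total length %s bp\n", x$n_segments,
              format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Independent verifier for a reported eccDNA cycle
#'
#' Walks the cycle and checks, directly against the raw joins (not the
#' graph), that every consecutive pair of oriented segments - including
#' the wrap-around - is supported by a join whose breakends fall within
#' tolerance of the exit boundary of one segment and the entry boundary of
#' the next, with the matching strands.
#'
#' @param cycle `ecc_cycle` object.
#' @param joins raw joins data frame.
#' @param tolerance_bp matching tolerance.
#' @return `TRUE` if every junction is supported, else `FALSE`.
#' @export
verify_cycle <- function(cycle, joins, tolerance_bp = 10000) {
  k <- cycle$n_segments
  segs <- cycle$segments
  endpoint <- function(i, side) {
    # side "exit": boundary left through; side "entry": boundary entered at
    o <- cycle$orientations[i]
    if (side == "exit") {
      if (o == "+") list(chrom = segs$chrom[i], pos = segs$end[i], strand = "+")
      else list(chrom = segs$chrom[i], pos = segs$start[i], strand = "-")
    } else {
      if (o == "+") list(chrom = segs$chrom[i], pos = segs$start[i], strand = "-")
      else list(chrom = segs$chrom[i], pos = segs$end[i], strand = "+")
    }
  }
  supported <- function(a, b) {
    hit <- function(chrom, pos, strand, jc, jp, js)
      jc == chrom & abs(jp - pos) <= tolerance_bp & js == strand
    any(hit(a$chrom, a$pos, a$strand, joins$chrom1, joins$pos1, joins$strand1) &
          hit(b$chrom, b$pos, b$strand, joins$chrom2, joins$pos2, joins$strand2)) ||
      any(hit(a$chrom, a$pos, a$strand, joins$chrom2, joins$pos2, joins$strand2) &
            hit(b$chrom, b$pos, b$strand, joins$chrom1, joins$pos1, joins$strand1))
  }
  for (i in seq_len(k)) {
    j <- if (i == k) 1 else i + 1
    if (!supported(endpoint(i, "exit"), endpoint(j, "entry"))) return(FALSE)
  }
  TRUE
}

#' Reconstruct eccDNA structures for one or more samples
#'
#' Pipeline composition: select amplified segments, build the amplicon
#' graph, enumerate cycles.  When the input carries a `sample` column the
#' reconstruction runs per sample.
#'
#' @param segments segment data frame.
#' @param joins joins data frame (with `sample` column when `segments`
#'   has one).
#' @param params parameters from [eccdna_params()].
#' @return list with one entry per sample: `cycles` (list of `ecc_cycle`),
#'   `graph`, `n_unmatched_joins`, `n_amplified_segments`.
#' @export
reconstruct_structures <- function(segments, joins, params = eccdna_params()) {
  one <- function(segs, jns) {
    nodes <- select_amplified_segments(segs, params$amp_threshold)
    graph <- build_amplicon_graph(nodes, jns, params$tolerance_bp)
    cycles <- find_cycles(graph, params$max_segments)
    list(cycles = cycles, graph = graph,
         n_unmatched_joins = length(graph$unmatched),
         n_amplified_segments = nrow(nodes))
  }
  if (!is.null(segments$sample) && length(unique(segments$sample)) >= 1) {
    samples <- unique(segments$sample)
    out <- lapply(samples, function(s) {
      jns <- if (!is.null(joins$sample)) joins[joins$sample == s, , drop = FALSE] else joins
      one(segments[segments$sample == s, , drop = FALSE], jns)
    })
    names(out) <- samples
    out
  } else {
    list(sample = one(segments, joins))
  }
}
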