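BIG_COST <- 1e9

#' Solve a linear assignment problem to optimality
#'
#' Dense Hungarian algorithm (compiled, O(n^3)). Non-finite entries are
#' treated as forbidden. Deterministic: cost ties are broken by the lowest
#' column index, so results are reproducible across runs.
#'
#' @param cost numeric cost matrix (square, or rectangular - padded
#'   internally with zero-cost dummy rows/columns).
#' @return list with `assignment` (for each row, the assigned column, NA for
#'   dummy-padded rows) and `total_cost` over real entries.
#' @export
solve_assignment <- function(cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  n <- max(n1, n2)
  m <- matrix(0, n, n)
  m[seq_len(n1), seq_len(n2)] <- cost
  m[!is.finite(m)] <- BIG_COST
  sol <- .lapjv_cpp(m)
  assignment <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) if (sol[i] <= n2) assignment[i] <- sol[i]
  real <- which(!is.na(assignment))
  structure(list(assignment = assignment,
                 total_cost = sum(cost[cbind(real, assignment[real])])),
            class = "assignment")
}

#' Parameters of the frame-to-frame link cost
#'
#' The cost of linking two nuclei in consecutive frames combines three
#' criteria: the Euclidean distance of their centroids, the similarity of
#' their features (mean intensity and area), and the local smoothness of the
#' trajectory (the turn angle relative to the track's previous step). All
#' three terms lie in \[0, 1\] and are mixed with weights `alpha`, `beta`,
#' `gamma` summing to one. Candidates farther apart than `gate_radius` are
#' never linked.
#'
#' @param alpha,beta,gamma weights of the distance, feature and smoothness
#'   terms; must sum to 1.
#' @param gate_radius gating radius in px, or `NULL` to estimate it from the
#'   data (see [estimate_gate_radius()]).
#' @return an object of class `link_cost_params`.
#' @export
link_cost_params <- function(alpha = 0.5, beta = 0.25, gamma = 0.25,
                             gate_radius = NULL) {
  if (abs(alpha + beta + gamma - 1) > 1e-9)
    stop("alpha + beta + gamma must equal 1")
  if (any(c(alpha, beta, gamma) < 0)) stop("weights must be non-negative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 gate_radius = gate_radius),
            class = "link_cost_params")
}

#' Estimate a gating radius from nearest-neighbour displacements
#'
#' Greedy pre-pass: for each consecutive frame pair, nearest-neighbour
#' distances from every object to the next frame; the gate is `k` times
#' their median. The default multiplier of 8 covers the long tail of
#' exponentially distributed per-frame path lengths (for an exponential
#' step length, 8 medians is about 5.5 means, beyond which fewer than 0.5%
#' of true steps fall), so gating rarely severs a genuine link.
#'
#' @param objects ObjectTable with a `frame` column.
#' @param k multiplier.
#' @return gate radius in px.
#' @export
estimate_gate_radius <- function(objects, k = 8) {
  frames <- sort(unique(objects$frame))
  dists <- c()
  for (i in seq_len(length(frames) - 1)) {
    a <- objects[objects$frame == frames[i], c("x", "y")]
    b <- objects[objects$frame == frames[i + 1], c("x", "y")]
    if (!nrow(a) || !nrow(b)) next
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    dists <- c(dists, sqrt(apply(d2, 1, min)))
  }
  if (!length(dists)) stop("no consecutive frames with objects")
  k * stats::median(dists)
}

link_cost_matrix <- function(objects_t, objects_t1, open_tracks, params) {
  n1 <- nrow(objects_t); n2 <- nrow(objects_t1)
  gate <- params$gate_radius
  d <- sqrt(outer(objects_t$x, objects_t1$x, "-")^2 +
            outer(objects_t$y, objects_t1$y, "-")^2)
  darea <- abs(outer(objects_t$area, objects_t1$area, "-")) /
    outer(objects_t$area, objects_t1$area, "+")
  dint <- abs(outer(objects_t$mean_intensity, objects_t1$mean_intensity, "-")) /
    outer(objects_t$mean_intensity, objects_t1$mean_intensity, "+")
  feature <- (darea + dint) / 2

  smooth <- matrix(0, n1, n2)
  if (!is.null(open_tracks) && nrow(open_tracks)) {
    prev <- open_tracks[match(objects_t$object_id, open_tracks$object_id), ]
    for (i in seq_len(n1)) {
      pdx <- prev$prev_dx[i]; pdy <- prev$prev_dy[i]
      if (is.na(pdx) || (pdx == 0 && pdy == 0)) next
      sdx <- objects_t1$x - objects_t$x[i]
      sdy <- objects_t1$y - objects_t$y[i]
      sl <- sqrt(sdx^2 + sdy^2)
      ct <- ifelse(sl > 0, (pdx * sdx + pdy * sdy) / (sqrt(pdx^2 + pdy^2) * sl), 1)
      smooth[i, ] <- (1 - ct) / 2
    }
  }
  cost <- params$alpha * d / gate + params$beta * feature +
    params$gamma * smooth
  cost[d > gate] <- Inf
  cost
}

#' Link objects of two consecutive frames
#'
#' Globally cost-optimal one-to-one correspondences via linear assignment
#' with virtual appear/disappear nodes priced at cost 1; a link is therefore
#' made only when its combined cost is competitive with opening/closing
#' tracks. See [link_cost_params()] for the cost model.
#'
#' @param objects_t,objects_t1 ObjectTables of frames t and t+1.
#' @param open_tracks optional data.frame (`object_id`, `prev_dx`, `prev_dy`)
#'   giving, per frame-t object, its track's previous step vector (used by
#'   the smoothness term; tracks with fewer than two points contribute 0).
#' @param params a [link_cost_params()] with a set `gate_radius`.
#' @return list: `links` (data.frame i, j, cost: row indices into the two
#'   tables), `unmatched_t`, `unmatched_t1` (row indices).
#' @export
link_frames <- function(objects_t, objects_t1, open_tracks = NULL, params) {
  n1 <- nrow(objects_t); n2 <- nrow(objects_t1)
  if (n1 == 0 || n2 == 0)
    return(list(links = data.frame(i = integer(), j = integer(),
                                   cost = numeric()),
                unmatched_t = seq_len(n1), unmatched_t1 = seq_len(n2)))
  if (is.null(params$gate_radius))
    stop("params$gate_radius must be set (see estimate_gate_radius)")
  cost <- link_cost_matrix(objects_t, objects_t1, open_tracks, params)

  n <- n1 + n2
  aug <- matrix(BIG_COST, n, n)
  aug[seq_len(n1), seq_len(n2)] <- cost
  aug[!is.finite(aug)] <- BIG_COST
  for (i in seq_len(n1)) aug[i, n2 + i] <- 1.0          # disappear
  for (j in seq_len(n2)) aug[n1 + j, j] <- 1.0          # appear
  aug[(n1 + 1):n, (n2 + 1):n] <- 0
  sol <- .lapjv_cpp(aug)

  links <- list()
  for (i in seq_len(n1)) {
    j <- sol[i]
    if (j <= n2 && is.finite(cost[i, j]))
      links[[length(links) + 1L]] <- data.frame(i = i, j = j,
                                                cost = cost[i, j])
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(i = integer(), j = integer(), cost = numeric())
  list(links = links,
       unmatched_t = setdiff(seq_len(n1), links$i),
       unmatched_t1 = setdiff(seq_len(n2), links$j))
}

#' Track objects across all frames
#'
#' Sequentially links consecutive frames ([link_frames()]); unmatched objects
#' close or open tracks. Frames are processed in increasing order of their
#' index; missing detections produce track breaks that [merge_breaks()] can
#' later repair.
#'
#' @param objects ObjectTable with `frame` column.
#' @param params [link_cost_params()]; a `NULL` gate radius is estimated
#'   from the data.
#' @return tracks data.frame: `track_id`, `frame`, `object_id`, `x`, `y`,
#'   `area`, `mean_intensity`, `circularity`.
#' @export
track_objects <- function(objects, params = link_cost_params()) {
  if (is.null(params$gate_radius))
    params$gate_radius <- estimate_gate_radius(objects)
  frames <- sort(unique(objects$frame))
  cols <- c("frame", "object_id", "x", "y", "area", "mean_intensity",
            "circularity")
  objects <- objects[order(objects$frame, objects$object_id), ]

  cur <- objects[objects$frame == frames[1], cols]
  cur$track_id <- seq_len(nrow(cur))
  next_tid <- nrow(cur) + 1L
  prev_step <- data.frame(track_id = cur$track_id, prev_dx = NA_real_,
                          prev_dy = NA_real_)
  out <- list(cur)

  for (fi in seq_len(length(frames) - 1)) {
    nxt <- objects[objects$frame == frames[fi + 1], cols]
    open_tracks <- data.frame(object_id = cur$object_id,
                              prev_dx = prev_step$prev_dx[
                                match(cur$track_id, prev_step$track_id)],
                              prev_dy = prev_step$prev_dy[
                                match(cur$track_id, prev_step$track_id)])
    lk <- link_frames(cur[, cols], nxt, open_tracks, params)
    nxt$track_id <- NA_integer_
    if (nrow(lk$links)) {
      nxt$track_id[lk$links$j] <- cur$track_id[lk$links$i]
    }
    new_n <- sum(is.na(nxt$track_id))
    nxt$track_id[is.na(nxt$track_id)] <- next_tid + seq_len(new_n) - 1L
    next_tid <- next_tid + new_n

    steps <- data.frame(track_id = nxt$track_id, prev_dx = NA_real_,
                        prev_dy = NA_real_)
    if (nrow(lk$links)) {
      steps$prev_dx[lk$links$j] <- nxt$x[lk$links$j] - cur$x[lk$links$i]
      steps$prev_dy[lk$links$j] <- nxt$y[lk$links$j] - cur$y[lk$links$i]
    }
    prev_step <- steps
    out[[length(out) + 1L]] <- nxt
    cur <- nxt
  }
  tracks <- do.call(rbind, out)
  tracks <- tracks[order(tracks$track_id, tracks$frame),
                   c("track_id", cols)]
  rownames(tracks) <- NULL
  tracks
}

#' Parameters of the mitosis-likelihood model
#'
#' The likelihood of a candidate division (a track ending at frame t with at
#' least two new tracks starting at t+1 within the gate) combines three
#' morphology terms, each in \[0, 1\]:
#' mother roundness `min(1, 1/circularity)` (mitotic cells round up),
#' daughter area similarity `1 - |a1 - a2| / (a1 + a2)`, and spatial
#' symmetry of the daughters about the mother
#' `1 - |d1 - d2| / (d1 + d2)`.
#'
#' @param w1,w2,w3 term weights, summing to 1.
#' @param l_min acceptance threshold on the likelihood.
#' @param gate_radius search radius (px) for daughter candidates.
#' @return an object of class `mitosis_params`.
#' @export
mitosis_params <- function(w1 = 1/3, w2 = 1/3, w3 = 1/3, l_min = 0.6,
                           gate_radius = NULL) {
  if (abs(w1 + w2 + w3 - 1) > 1e-9) stop("w1 + w2 + w3 must equal 1")
  structure(list(w1 = w1, w2 = w2, w3 = w3, l_min = l_min,
                 gate_radius = gate_radius), class = "mitosis_params")
}

#' Likelihood of one candidate mitosis
#'
#' @param mother_circularity circularity of the mother in its final frame.
#' @param daughter_areas length-2 vector of daughter areas.
#' @param daughter_dists length-2 vector of mother-to-daughter distances.
#' @param params [mitosis_params()].
#' @return likelihood in \[0, 1\].
#' @export
mitosis_likelihood <- function(mother_circularity, daughter_areas,
                               daughter_dists, params = mitosis_params()) {
  roundness <- min(1, max(0, 1 / mother_circularity))
  similarity <- 1 - abs(diff(daughter_areas)) / sum(daughter_areas)
  symmetry <- if (sum(daughter_dists) > 0)
    1 - abs(diff(daughter_dists)) / sum(daughter_dists) else 1
  params$w1 * roundness + params$w2 * similarity + params$w3 * symmetry
}

#' Detect mitosis events among tracked cells
#'
#' Two candidate patterns are scored at every frame transition t -> t+1
#' where at least one new track starts within `gate_radius` of a mother
#' candidate:
#' \itemize{
#'   \item a track ending at t with two or more new tracks starting at t+1
#'     (the linker left both daughters unexplained);
#'   \item a track passing through t -> t+1 with one new track starting at
#'     t+1 beside it (the linker continued the mother into one daughter; the
#'     hypothesis pairs that continuation with the new track).
#' }
#' Each candidate pair is scored with [mitosis_likelihood()]; pairs with
#' likelihood at least `l_min` are accepted greedily in decreasing
#' likelihood order. For an accepted continuation pair the mother track is
#' split at t+1 and the post-division part receives a fresh track id, so
#' every accepted mitosis ends its mother and starts two daughters. The
#' updated tracks are attached as `attr(events, "tracks")`.
#'
#' @param tracks tracks data.frame from [track_objects()].
#' @param params [mitosis_params()]; a `NULL` gate radius falls back to 8x
#'   the median per-frame displacement of the tracks.
#' @return data.frame: `mother_id`, `daughter_id_1`, `daughter_id_2`,
#'   `frame` (mother's final frame), `likelihood`; tracks (with splits
#'   applied) in `attr(, "tracks")`.
#' @export
detect_mitosis <- function(tracks, params = mitosis_params()) {
  empty <- data.frame(mother_id = integer(), daughter_id_1 = integer(),
                      daughter_id_2 = integer(), frame = integer(),
                      likelihood = numeric())
  attr(empty, "tracks") <- tracks
  if (!nrow(tracks)) return(empty)
  if (is.null(params$gate_radius)) {
    steps <- unlist(lapply(split(tracks, tracks$track_id), function(tr) {
      if (nrow(tr) < 2) return(NULL)
      sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    }))
    params$gate_radius <- if (!length(steps)) 10 else 8 * stats::median(steps)
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  info <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    data.frame(track_id = tr$track_id[1],
               first_frame = tr$frame[1], last_frame = tr$frame[nrow(tr)],
               x0 = tr$x[1], y0 = tr$y[1], area0 = tr$area[1])
  }))
  last_frame <- max(tracks$frame)

  row_at <- function(id, f) {
    r <- tracks[tracks$track_id == id & tracks$frame == f, , drop = FALSE]
    if (nrow(r)) r[1, ] else NULL
  }

  cands <- list()
  for (t in sort(unique(tracks$frame))) {
    if (t >= last_frame) break
    # daughter candidates must persist beyond their first frame (single-
    # frame tracks are almost always detection artefacts), except at the
    # end of the movie where persistence cannot be observed
    starters <- info[info$first_frame == t + 1 &
                     (info$last_frame > info$first_frame |
                        info$first_frame == last_frame), , drop = FALSE]
    if (!nrow(starters)) next
    mothers <- info[info$first_frame <= t & info$last_frame >= t, ,
                    drop = FALSE]
    for (mi in seq_len(nrow(mothers))) {
      m <- mothers[mi, ]
      mrow <- row_at(m$track_id, t)
      if (is.null(mrow)) next
      dd <- sqrt((starters$x0 - mrow$x)^2 + (starters$y0 - mrow$y)^2)
      new_d <- starters[dd <= params$gate_radius, , drop = FALSE]
      new_dist <- dd[dd <= params$gate_radius]
      if (!nrow(new_d)) next
      cont <- if (m$last_frame > t) row_at(m$track_id, t + 1) else NULL
      if (is.null(cont)) {
        if (nrow(new_d) < 2) next
        prs <- utils::combn(nrow(new_d), 2)
        for (c_ in seq_len(ncol(prs))) {
          a <- prs[1, c_]; b <- prs[2, c_]
          L <- mitosis_likelihood(mrow$circularity,
                                  c(new_d$area0[a], new_d$area0[b]),
                                  c(new_dist[a], new_dist[b]), params)
          cands[[length(cands) + 1L]] <- data.frame(
            mother_id = m$track_id, frame = t, type = "ends",
            d1 = new_d$track_id[a], d2 = new_d$track_id[b], likelihood = L)
        }
      } else {
        cont_dist <- sqrt((cont$x - mrow$x)^2 + (cont$y - mrow$y)^2)
        for (a in seq_len(nrow(new_d))) {
          L <- mitosis_likelihood(mrow$circularity,
                                  c(cont$area, new_d$area0[a]),
                                  c(cont_dist, new_dist[a]), params)
          cands[[length(cands) + 1L]] <- data.frame(
            mother_id = m$track_id, frame = t, type = "continues",
            d1 = NA_integer_, d2 = new_d$track_id[a], likelihood = L)
        }
      }
    }
  }
  if (!length(cands)) return(empty)
  cands <- do.call(rbind, cands)
  cands <- cands[cands$likelihood >= params$l_min, , drop = FALSE]
  if (!nrow(cands)) return(empty)
  cands <- cands[order(-cands$likelihood, cands$mother_id, cands$frame), ,
                 drop = FALSE]

  # greedy acceptance in decreasing likelihood: one division per
  # (mother, frame); a track may divide repeatedly at increasing frames
  # (the linker threads mother -> daughter -> granddaughter through one id;
  # splits are applied chronologically below); each new track serves as a
  # daughter at most once
  used_new <- integer(); used_mother <- character()
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    mk <- paste(cands$mother_id[i], cands$frame[i])
    ds <- c(cands$d1[i], cands$d2[i])
    ds <- ds[!is.na(ds)]
    if (mk %in% used_mother || any(ds %in% used_new)) next
    keep[i] <- TRUE
    used_mother <- c(used_mother, mk)
    used_new <- c(used_new, ds)
  }
  acc <- cands[keep, , drop = FALSE]
  if (!nrow(acc)) return(empty)
  acc <- acc[order(acc$frame), , drop = FALSE]

  # per original track: segments (start_frame -> current id) created by
  # earlier splits, so later events resolve to the segment active at their
  # frame
  next_id <- max(tracks$track_id) + 1L
  segments <- list()
  resolve <- function(orig, f) {
    segs <- segments[[as.character(orig)]]
    if (is.null(segs)) return(orig)
    ok <- segs$start <= f
    if (!any(ok)) orig else segs$id[max(which(ok))]
  }
  events <- list()
  for (i in seq_len(nrow(acc))) {
    e <- acc[i, ]
    mid <- resolve(e$mother_id, e$frame)
    if (e$type == "continues") {
      sel <- tracks$track_id == mid & tracks$frame >= e$frame + 1
      if (!any(sel)) next
      tracks$track_id[sel] <- next_id
      key <- as.character(e$mother_id)
      segments[[key]] <- rbind(segments[[key]],
                               data.frame(start = e$frame + 1, id = next_id))
      d1 <- next_id
      next_id <- next_id + 1L
    } else d1 <- e$d1
    events[[length(events) + 1L]] <-
      data.frame(mother_id = mid, daughter_id_1 = d1,
                 daughter_id_2 = e$d2, frame = e$frame,
                 likelihood = e$likelihood)
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  attr(out, "tracks") <- tracks
  out
}

#' Merge obvious trajectory breaks
#'
#' A track ending at frame t and a track starting at frame t+g with
#' `2 <= g <= max_gap + 1` (i.e. 1..`max_gap` missing frames) whose
#' end-to-start distance is at most `gate_radius * g` are merged, choosing
#' the globally minimal total distance one-to-one pairing. Chains of merges
#' are resolved transitively; the merged track keeps the earliest id.
#'
#' @param tracks tracks data.frame.
#' @param max_gap maximal number of missing frames bridged.
#' @param gate_radius per-frame gating radius in px.
#' @param exclude_starts track ids never used as continuations (e.g. mitosis
#'   daughters, whose start is a division, not a break).
#' @param exclude_ends track ids never continued (e.g. mitosis mothers, whose
#'   end is a division, not a break).
#' @return tracks data.frame with merged ids; merged pairs in
#'   `attr(, "merges")`, the full id remapping in `attr(, "remap")`.
#' @export
merge_breaks <- function(tracks, max_gap = 3, gate_radius,
                         exclude_starts = NULL, exclude_ends = NULL) {
  info <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    data.frame(track_id = tr$track_id[1], first_frame = tr$frame[1],
               last_frame = tr$frame[n], x0 = tr$x[1], y0 = tr$y[1],
               xe = tr$x[n], ye = tr$y[n])
  }))
  ends <- info[!info$track_id %in% exclude_ends, , drop = FALSE]
  starts <- info[!info$track_id %in% exclude_starts, , drop = FALSE]
  ne <- nrow(ends); ns <- nrow(starts)
  if (!ne || !ns) { attr(tracks, "merges") <- NULL; return(tracks) }
  g <- outer(rep(1, ne), starts$first_frame) - outer(ends$last_frame, rep(1, ns))
  d <- sqrt(outer(ends$xe, starts$x0, "-")^2 + outer(ends$ye, starts$y0, "-")^2)
  allowed <- g >= 2 & g <= max_gap + 1 & d <= gate_radius * g &
    outer(ends$track_id, starts$track_id, "!=")
  if (!any(allowed)) { attr(tracks, "merges") <- NULL; return(tracks) }
  skip <- gate_radius * (max_gap + 1) + 1
  n <- ne + ns
  aug <- matrix(BIG_COST, n, n)
  cm <- d; cm[!allowed] <- BIG_COST
  aug[seq_len(ne), seq_len(ns)] <- cm
  for (i in seq_len(ne)) aug[i, ns + i] <- skip
  for (j in seq_len(ns)) aug[ne + j, j] <- skip
  aug[(ne + 1):n, (ns + 1):n] <- 0
  sol <- .lapjv_cpp(aug)
  remap <- setNames(info$track_id, info$track_id)
  merges <- list()
  for (i in seq_len(ne)) {
    j <- sol[i]
    if (j <= ns && allowed[i, j]) {
      merges[[length(merges) + 1L]] <-
        data.frame(from = starts$track_id[j], into = ends$track_id[i])
      remap[as.character(starts$track_id[j])] <- ends$track_id[i]
    }
  }
  # resolve chains (B merged into A, C merged into B -> C into A)
  repeat {
    tgt <- remap[as.character(remap)]
    if (all(tgt == remap)) break
    remap <- tgt
  }
  tracks$track_id <- as.integer(remap[as.character(tracks$track_id)])
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  attr(tracks, "merges") <- if (length(merges)) do.call(rbind, merges) else NULL
  attr(tracks, "remap") <- remap
  tracks
}

#' Build the cell lineage forest
#'
#' @param tracks tracks data.frame.
#' @param mitoses mitosis table from [detect_mitosis()].
#' @return object of class `lineage_tree`: `nodes` (per track: id, first and
#'   last frame, number of points), `edges` (mother -> daughter, two per
#'   mitosis), `mitoses`, `roots`.
#' @export
build_lineage <- function(tracks, mitoses) {
  nodes <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    data.frame(track_id = tr$track_id[1], first_frame = min(tr$frame),
               last_frame = max(tr$frame), n_points = nrow(tr))
  }))
  rownames(nodes) <- NULL
  edges <- if (nrow(mitoses))
    data.frame(mother = rep(mitoses$mother_id, each = 2),
               daughter = as.vector(rbind(mitoses$daughter_id_1,
                                          mitoses$daughter_id_2)),
               frame = rep(mitoses$frame, each = 2),
               likelihood = rep(mitoses$likelihood, each = 2))
  else data.frame(mother = integer(), daughter = integer(),
                  frame = integer(), likelihood = numeric())
  if (anyDuplicated(edges$daughter))
    stop("a daughter track has two mothers; upstream tracking is inconsistent")
  roots <- setdiff(nodes$track_id, edges$daughter)
  structure(list(nodes = nodes, edges = edges, mitoses = mitoses,
                 roots = roots), class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage forest: %d tracks, %d mitoses, %d roots\n",
              nrow(x$nodes), nrow(x$mitoses), length(x$roots)))
  invisible(x)
}

#' Mitotic index of a tracked movie
#'
#' Accepted mitoses divided by the total cell-observation time: the summed
#' elapsed observed time of all tracks, in cell-hours.
#'
#' @param lineage a `lineage_tree`.
#' @param tracks tracks data.frame.
#' @param frame_interval min per frame.
#' @return list: `rate` (events per cell per hour), `n_events`, `cell_hours`.
#' @export
mitotic_index <- function(lineage, tracks, frame_interval) {
  per_track <- tapply(tracks$frame, tracks$track_id,
                      function(f) max(f) - min(f))
  cell_hours <- sum(per_track) * frame_interval / 60
  if (cell_hours <= 0) stop("zero total observation time")
  n <- nrow(lineage$mitoses)
  list(rate = n / cell_hours, n_events = n, cell_hours = cell_hours)
}

#' Full tracking stage: link, detect mitoses, merge breaks, build lineage
#'
#' @param objects ObjectTable with `frame` column.
#' @param link_params [link_cost_params()].
#' @param mito_params [mitosis_params()].
#' @param max_gap maximal bridged gap for [merge_breaks()].
#' @return list: `tracks`, `mitoses`, `lineage`, `gate_radius`.
#' @export
track_cells <- function(objects, link_params = link_cost_params(),
                        mito_params = mitosis_params(), max_gap = 3) {
  if (is.null(link_params$gate_radius))
    link_params$gate_radius <- estimate_gate_radius(objects)
  tracks <- track_objects(objects, link_params)
  if (is.null(mito_params$gate_radius))
    mito_params$gate_radius <- link_params$gate_radius
  mitoses <- detect_mitosis(tracks, mito_params)
  tracks <- attr(mitoses, "tracks")
  daughters <- c(mitoses$daughter_id_1, mitoses$daughter_id_2)
  tracks <- merge_breaks(tracks, max_gap = max_gap,
                         gate_radius = link_params$gate_radius,
                         exclude_starts = daughters,
                         exclude_ends = mitoses$mother_id)
  remap <- attr(tracks, "remap")
  if (!is.null(remap) && nrow(mitoses)) {
    rm_id <- function(id) as.integer(remap[as.character(id)])
    mitoses$mother_id <- rm_id(mitoses$mother_id)
    mitoses$daughter_id_1 <- rm_id(mitoses$daughter_id_1)
    mitoses$daughter_id_2 <- rm_id(mitoses$daughter_id_2)
  }
  lineage <- build_lineage(tracks, mitoses)
  list(tracks = tracks, mitoses = mitoses, lineage = lineage,
       gate_radius = link_params$gate_radius)
}
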