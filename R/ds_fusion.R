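# Dempster-Shafer combination of expert opinions about candidate causal arcs.
#
# Each opinion is a basic probability assignment (BPA) over the binary frame
# {present, absent}; ignorance is mass on the whole frame. Multiple experts
# are fused with Dempster's rule: mass products are assigned to the
# intersections of focal sets and the conflicting (empty-intersection) mass K
# is renormalized away by 1/(1-K).

EMPTY_KEY <- "\x01empty"

subset_key <- function(elements, frame) {
  if (!length(elements)) return(EMPTY_KEY)
  paste(frame[sort(match(elements, frame))], collapse = "+")
}

key_elements <- function(key) {
  if (identical(key, EMPTY_KEY)) character(0) else strsplit(key, "+", fixed = TRUE)[[1]]
}

#' Basic probability assignment
#'
#' Constructs a mass function over subsets of a finite frame of discernment.
#' Masses must be non-negative, sum to 1 (tolerance 1e-9), and the empty set
#' carries no mass.
#'
#' @param frame Character vector of mutually exclusive hypotheses.
#' @param masses Named numeric vector; each name is a subset written as its
#'   elements joined by `+` (e.g. `"present"`, `"present+absent"`).
#' @return Object of class `bpa`.
#' @examples
#' bpa(c("present", "absent"), c(present = 0.6, `present+absent` = 0.4))
#' @export
bpa <- function(frame, masses) {
  if (!is.character(frame) || !length(frame) || anyDuplicated(frame)) {
    abort_escbn("`frame` must be a non-empty set of unique hypotheses.",
                "escbn_frame_error")
  }
  if (!is.numeric(masses) || is.null(names(masses))) {
    abort_escbn("`masses` must be a named numeric vector.", "escbn_bpa_error")
  }
  canon <- vapply(names(masses), function(k) {
    els <- key_elements(k)
    if (!all(els %in% frame)) {
      abort_escbn(sprintf("Focal set '%s' is not a subset of the frame.", k),
                  "escbn_bpa_error")
    }
    subset_key(els, frame)
  }, character(1))
  m <- tapply(as.numeric(masses), canon, sum)
  m <- stats::setNames(as.numeric(m), names(m))
  if (any(m < -1e-12)) {
    abort_escbn("Masses must be non-negative.", "escbn_bpa_error")
  }
  if (EMPTY_KEY %in% names(m) && m[[EMPTY_KEY]] > 1e-12) {
    abort_escbn("The empty set must carry zero mass.", "escbn_bpa_error")
  }
  m <- m[names(m) != EMPTY_KEY & m > 0]
  if (abs(sum(m) - 1) > 1e-9) {
    abort_escbn(sprintf("Masses sum to %.12f, not 1.", sum(m)), "escbn_bpa_error")
  }
  structure(list(frame = frame, masses = m), class = "bpa")
}

#' @export
print.bpa <- function(x, ...) {
  cat("<bpa> frame {", paste(x$frame, collapse = ", "), "}\n")
  for (k in names(x$masses)) {
    cat(sprintf("  m(%s) = %.6f\n", ifelse(k == EMPTY_KEY, "{}", k), x$masses[[k]]))
  }
  invisible(x)
}

check_common_frame <- function(bpas) {
  if (!length(bpas)) {
    abort_escbn("At least one BPA is required.", "escbn_bpa_error")
  }
  frame <- bpas[[1]]$frame
  for (b in bpas) {
    if (!inherits(b, "bpa") || !identical(b$frame, frame)) {
      abort_escbn("All BPAs must share the same frame of discernment.",
                  "escbn_frame_error")
    }
  }
  frame
}

# Unnormalized sequential product keeping the empty set, so that the mass on
# "" after processing all inputs equals the N-way conflict K.
ds_product <- function(bpas) {
  frame <- check_common_frame(bpas)
  acc <- bpas[[1]]$masses
  for (b in bpas[-1]) {
    out <- numeric(0)
    for (k1 in names(acc)) {
      e1 <- key_elements(k1)
      for (k2 in names(b$masses)) {
        inter <- if (identical(k1, EMPTY_KEY)) character(0) else intersect(e1, key_elements(k2))
        key <- subset_key(inter, frame)
        out[key] <- (if (key %in% names(out)) out[[key]] else 0) +
          acc[[k1]] * b$masses[[k2]]
      }
    }
    acc <- out
  }
  acc
}

#' Conflict coefficient of a set of BPAs
#'
#' The total mass that Dempster's rule assigns to contradictory combinations:
#' the sum, over tuples of focal sets (one per source) with empty
#' intersection, of the product of their masses. `K = 0` when no conflicting
#' tuple has positive mass; `K = 1` means total conflict.
#'
#' @param bpas List of [bpa()] objects over a common frame.
#' @return A number in `[0, 1]`.
#' @export
ds_conflict <- function(bpas) {
  acc <- ds_product(bpas)
  k <- if (EMPTY_KEY %in% names(acc)) acc[[EMPTY_KEY]] else 0
  min(max(k, 0), 1)
}

#' Combine BPAs with Dempster's rule
#'
#' The orthogonal sum: for each non-empty subset A, the fused mass is the sum
#' of mass products over focal-set tuples whose intersection equals A,
#' normalized by `1/(1-K)` where K is the conflict coefficient. The result is
#' independent of input order and has the vacuous BPA as identity element.
#'
#' @param bpas List of [bpa()] objects over a common frame.
#' @return A fused [bpa()].
#' @export
ds_combine <- function(bpas) {
  frame <- check_common_frame(bpas)
  acc <- ds_product(bpas)
  k <- if (EMPTY_KEY %in% names(acc)) acc[[EMPTY_KEY]] else 0
  if (k >= 1 - 1e-12) {
    abort_escbn("Total conflict (K = 1): Dempster combination is undefined.",
                "escbn_total_conflict")
  }
  m <- acc[names(acc) != EMPTY_KEY] / (1 - k)
  bpa(frame, m)
}

#' Fuse per-edge expert opinions
#'
#' Takes a long tibble of expert opinions about candidate arcs (one row per
#' expert and ordered node pair, with masses on "arc present", "arc absent"
#' and the whole frame) and combines the experts for each arc with Dempster's
#' rule.
#'
#' @param opinions Tibble with columns `expert_id`, `from`, `to`,
#'   `m_present`, `m_absent`, `m_theta`; the three masses must sum to 1 per
#'   row and each expert may assess each ordered pair at most once.
#' @return Tibble with one row per arc: `from`, `to`, `n_experts`, fused
#'   `m_present`, `m_absent`, `m_theta`, and the conflict coefficient `k`.
#' @export
fuse_edge_opinions <- function(opinions) {
  needed <- c("expert_id", "from", "to", "m_present", "m_absent", "m_theta")
  if (!all(needed %in% names(opinions))) {
    abort_escbn(
      sprintf("`opinions` needs columns %s.", paste(needed, collapse = ", ")),
      "escbn_data_error"
    )
  }
  if (any(opinions$from == opinions$to)) {
    abort_escbn("Opinions contain a self-loop candidate edge.", "escbn_data_error")
  }
  dup <- duplicated(opinions[, c("expert_id", "from", "to")])
  if (any(dup)) {
    abort_escbn("An expert has more than one opinion on the same ordered pair.",
                "escbn_data_error")
  }
  frame <- c("present", "absent")
  edge_key <- paste(opinions$from, opinions$to, sep = "\r")
  groups <- split(seq_len(nrow(opinions)), edge_key)
  rows <- lapply(groups, function(ix) {
    bpas <- lapply(ix, function(i) {
      bpa(frame, c(
        present = opinions$m_present[[i]],
        absent = opinions$m_absent[[i]],
        `present+absent` = opinions$m_theta[[i]]
      ))
    })
    k <- ds_conflict(bpas)
    fused <- tryCatch(ds_combine(bpas), error = function(e) {
      if (inherits(e, "escbn_total_conflict")) {
        abort_escbn(
          sprintf("Total conflict fusing edge %s -> %s.",
                  opinions$from[[ix[1]]], opinions$to[[ix[1]]]),
          "escbn_total_conflict"
        )
      }
      stop(e)
    })
    get_m <- function(key) {
      if (key %in% names(fused$masses)) fused$masses[[key]] else 0
    }
    tibble::tibble(
      from = opinions$from[[ix[1]]],
      to = opinions$to[[ix[1]]],
      n_experts = length(ix),
      m_present = get_m("present"),
      m_absent = get_m("absent"),
      m_theta = get_m("present+absent"),
      k = k
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$from, .data$to)
}

#' Turn fused beliefs into edge decisions
#'
#' An arc is accepted when the fused mass on "present" reaches
#' `accept_threshold`, rejected when the mass on "absent" reaches
#' `reject_threshold`, and uncertain otherwise; uncertain arcs go on to
#' mutual-information arbitration. Accepted arcs are oriented from the lower
#' causal tier to the higher; same-tier candidates are rejected because the
#' node taxonomy admits no within-tier causation.
#'
#' @param fused Output of [fuse_edge_opinions()].
#' @param nodes Node-set tibble supplying tiers.
#' @param accept_threshold Belief needed to accept an arc (default 0.7).
#' @param reject_threshold Belief in absence needed to reject (defaults to
#'   `accept_threshold`).
#' @return Tibble `from`, `to`, masses, `k`, and `status` in
#'   accepted/rejected/uncertain.
#' @export
decide_edges <- function(fused, nodes = canonical_nodes(),
                         accept_threshold = 0.7,
                         reject_threshold = accept_threshold) {
  stopifnot_scalar_number(accept_threshold, "accept_threshold", 0, 1)
  stopifnot_scalar_number(reject_threshold, "reject_threshold", 0, 1)
  if (reject_threshold > accept_threshold || accept_threshold >= 1 ||
      reject_threshold <= 0) {
    abort_escbn("Need 0 < reject_threshold <= accept_threshold < 1.",
                "escbn_config_error")
  }
  out <- fused
  # orient along increasing causal rank
  tiers_from <- vapply(out$from, function(v) rank_of(nodes, v), numeric(1))
  tiers_to <- vapply(out$to, function(v) rank_of(nodes, v), numeric(1))
  flip <- tiers_from > tiers_to
  if (any(flip)) {
    tmp <- out$from[flip]
    out$from[flip] <- out$to[flip]
    out$to[flip] <- tmp
  }
  same_tier <- tiers_from == tiers_to
  status <- ifelse(
    out$m_present >= accept_threshold, "accepted",
    ifelse(out$m_absent >= reject_threshold, "rejected", "uncertain")
  )
  status[same_tier] <- "rejected"
  out$status <- status
  out
}

#' Read expert opinions from JSON
#'
#' The file is an array of `{expert_id, opinions: [{from, to, m_present,
#' m_absent, m_theta}]}` objects with the three masses summing to 1.
#'
#' @param path JSON file path.
#' @return Long opinions tibble suitable for [fuse_edge_opinions()].
#' @export
read_expert_opinions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rows <- lapply(raw, function(ex) {
    dplyr::bind_rows(lapply(ex$opinions, function(op) {
      tibble::tibble(
        expert_id = as.character(ex$expert_id),
        from = op$from, to = op$to,
        m_present = as.numeric(op$m_present),
        m_absent = as.numeric(op$m_absent),
        m_theta = as.numeric(op$m_theta)
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  bad <- abs(out$m_present + out$m_absent + out$m_theta - 1) > 1e-9
  if (any(bad)) {
    abort_escbn(sprintf("Opinion masses in row %d do not sum to 1.", which(bad)[1]),
                "escbn_bpa_error")
  }
  out
}

#' Write expert opinions to JSON
#'
#' @param opinions Long opinions tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expert_opinions <- function(opinions, path) {
  split_ops <- split(opinions, opinions$expert_id)
  payload <- lapply(names(split_ops), function(id) {
    df <- split_ops[[id]]
    list(
      expert_id = id,
      opinions = lapply(seq_len(nrow(df)), function(i) {
        list(from = df$from[[i]], to = df$to[[i]],
             m_present = df$m_present[[i]], m_absent = df$m_absent[[i]],
             m_theta = df$m_theta[[i]])
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
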