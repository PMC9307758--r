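# Randomized-crossover worklist triage simulation and radiological time
# metrics.  A block is one radiologist's worklist at one time (nominally 23
# scans); wait time (WT), report turnaround time (TAT) and reading time
# (RT) are measured from the opening of the block.

#' Partition cases into two groups and randomized blocks
#'
#' Cases are shuffled and split near-equally (sizes differ by at most 1,
#' larger group first, so 1795 cases split 898/897).  Each group is cut
#' into `floor(n/block_size)` blocks; the remainder is absorbed into the
#' final block (898 cases at block size 23 give 39 blocks, the last of 24).
#' Block reading orders are permuted independently for each of the two
#' sessions.
#'
#' @param case_ids character vector (>= 2 cases).
#' @param block_size nominal block size (default 23).
#' @param seed RNG seed.
#' @return list with `groups` (list `A`, `B` of block lists) and
#'   `session_order` (per session, per group, a permutation of block
#'   indices).
#' @export
partition_and_randomize <- function(case_ids, block_size = 23L, seed = 1L) {
  if (block_size < 1) stop("`block_size` must be >= 1", call. = FALSE)
  n <- length(case_ids)
  if (n < 2) stop("need at least 2 cases", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sample(case_ids)
  nA <- ceiling(n / 2)
  split_blocks <- function(v) {
    m <- length(v)
    nb <- max(1L, m %/% block_size)
    sizes <- rep(block_size, nb)
    sizes[nb] <- m - block_size * (nb - 1L)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_len(nb), function(i) v[starts[i]:ends[i]])
  }
  groups <- list(A = split_blocks(ids[seq_len(nA)]),
                 B = split_blocks(ids[(nA + 1):n]))
  session_order <- lapply(1:2, function(s)
    list(A = sample(length(groups$A)), B = sample(length(groups$B))))
  names(session_order) <- c("session1", "session2")
  list(groups = groups, session_order = session_order)
}

#' Reprioritize a block's worklist by anomaly score
#'
#' Cases at or above the threshold are flagged and moved to the front,
#' sorted by descending score; the remaining cases keep their original
#' relative order.  The output is a permutation of the input.
#'
#' @param block character vector of case ids in original order.
#' @param scores named numeric vector covering every case in the block.
#' @param threshold flagging threshold (positive call: score >= threshold).
#' @return data frame `case_id, score, flagged` in reading order.
#' @export
reprioritize <- function(block, scores, threshold) {
  missing <- setdiff(block, names(scores))
  if (length(missing))
    stop("missing scores for: ", paste(missing, collapse = ", "), call. = FALSE)
  s <- scores[block]
  flag <- s >= threshold
  front <- order(-s[flag])
  out <- c(block[flag][front], block[!flag])
  data.frame(case_id = out, score = as.numeric(scores[out]),
             flagged = as.logical(flag[out]), stringsAsFactors = FALSE)
}

#' Log-normal reader model
#'
#' Reading times are drawn from a log-normal with a configurable median
#' (default 30 s, the scale of expert brain-CT reading times) and log-SD.
#'
#' @param median_rt median reading time in seconds.
#' @param sdlog log-scale SD.
#' @return function(case_id) -> seconds (uses the current RNG stream).
#' @export
reader_model_lognormal <- function(median_rt = 30, sdlog = 0.28) {
  force(median_rt); force(sdlog)
  function(case_id) stats::rlnorm(1, meanlog = log(median_rt), sdlog = sdlog)
}

#' Simulate a reading session
#'
#' Within each block, cases are opened strictly in worklist order,
#' back-to-back from the block's opening at t = 0; a case closes after its
#' reading time and its report is filed at closing.
#'
#' @param worklists list of character vectors (one ordered worklist per
#'   block).
#' @param reader_model function(case_id) -> positive reading time in
#'   seconds.
#' @param seed RNG seed for the reader model.
#' @return event-log data frame `case_id, block, block_open, case_open,
#'   case_close, report_time` (seconds).
#' @export
run_session <- function(worklists, reader_model, seed = 1L) {
  set.seed(as.integer(seed))
  rows <- vector("list", length(worklists))
  for (b in seq_along(worklists)) {
    ids <- worklists[[b]]
    rts <- vapply(ids, function(cid) reader_model(cid), 0)
    bad <- which(!is.finite(rts) | rts <= 0)
    if (length(bad))
      stop("reader model returned a non-positive duration for ", ids[bad[1]],
           call. = FALSE)
    close_t <- cumsum(rts)
    open_t <- c(0, utils::head(close_t, -1L))
    rows[[b]] <- data.frame(case_id = ids, block = b, block_open = 0,
                            case_open = open_t, case_close = close_t,
                            report_time = close_t, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compute WT / TAT / RT from an event log
#'
#' Wait time is the case opening minus the block opening; turnaround time
#' the report time minus the block opening; reading time the case closing
#' minus the case opening.
#'
#' @param log event-log data frame as from [run_session()].
#' @return data frame `case_id, WT, TAT, RT` (seconds).
#' @export
compute_time_metrics <- function(log) {
  need <- c("case_id", "block_open", "case_open", "case_close", "report_time")
  if (!all(need %in% names(log)))
    stop("event log needs columns ", paste(need, collapse = ", "), call. = FALSE)
  bad <- which(log$case_open > log$case_close | log$report_time < log$case_open |
                 log$case_open < log$block_open)
  if (length(bad))
    stop("event-log invariant violated for case ", log$case_id[bad[1]],
         call. = FALSE)
  data.frame(case_id = log$case_id,
             WT = log$case_open - log$block_open,
             TAT = log$report_time - log$block_open,
             RT = log$case_close - log$case_open,
             stringsAsFactors = FALSE)
}

#' Run the full randomized-crossover triage simulation
#'
#' Cases are partitioned into groups A and B and blocks; in session 1 group
#' A is read without triage and group B with it, in session 2 the
#' assignment is crossed over.  Each reader reads every block in both
#' sessions; pre-triage metrics pool the without-triage readings and
#' post-triage metrics the with-triage readings (pooled reader-case
#' observations).
#'
#' @param case_ids character vector of case ids.
#' @param scores named anomaly scores for every case.
#' @param threshold triage threshold.
#' @param n_readers number of independent readers (default 2).
#' @param block_size nominal block size.
#' @param seed RNG seed.
#' @param reader_model function(case_id) -> seconds, default
#'   [reader_model_lognormal()].
#' @return list with `pre` and `post` (data frames `case_id, reader, WT,
#'   TAT, RT`), and `partition`.
#' @export
run_crossover_simulation <- function(case_ids, scores, threshold,
                                     n_readers = 2L, block_size = 23L,
                                     seed = 1L,
                                     reader_model = reader_model_lognormal()) {
  part <- partition_and_randomize(case_ids, block_size, seed)
  with_tri <- function(blocks) lapply(blocks, function(b)
    reprioritize(b, scores, threshold)$case_id)
  arms <- list(
    session1 = list(A = list(triage = FALSE, wl = part$groups$A),
                    B = list(triage = TRUE, wl = with_tri(part$groups$B))),
    session2 = list(A = list(triage = TRUE, wl = with_tri(part$groups$A)),
                    B = list(triage = FALSE, wl = part$groups$B)))
  pre <- list(); post <- list()
  for (rd in seq_len(n_readers)) {
    for (sx in names(arms)) {
      for (gx in c("A", "B")) {
        arm <- arms[[sx]][[gx]]
        ord <- part$session_order[[sx]][[gx]]
        logd <- run_session(arm$wl[ord], reader_model,
                            seed = seed + 1000L * rd + 10L * match(sx, names(arms)) +
                              match(gx, c("A", "B")))
        tm <- compute_time_metrics(logd)
        tm$reader <- rd
        if (arm$triage) post[[length(post) + 1]] <- tm else
          pre[[length(pre) + 1]] <- tm
      }
    }
  }
  list(pre = do.call(rbind, pre), post = do.call(rbind, post),
       partition = part)
}

.q25 <- function(x) stats::quantile(x, 0.25, names = FALSE, type = 7)
.q75 <- function(x) stats::quantile(x, 0.75, names = FALSE, type = 7)

#' Summarize paired pre/post outcomes
#'
#' For each subgroup and each metric (WT, TAT, RT): median (IQR, linear
#' interpolation), mean (SD), min-max, the median paired difference, the
#' Wilcoxon signed-rank p-value for the pre/post comparison, and the
#' Wilcoxon rank-sum p-value comparing the subgroup's paired differences
#' with the rest of the cohort.
#'
#' @param pre,post data frames `case_id, WT, TAT, RT` (and optionally
#'   `reader`); paired by `case_id` (and reader when present).
#' @param groups named character vector mapping case_id to subgroup label.
#' @return data frame with one row per (subgroup, metric).
#' @export
summarize_outcomes <- function(pre, post, groups = NULL) {
  key <- function(d) if ("reader" %in% names(d))
    paste(d$case_id, d$reader, sep = "#") else d$case_id
  pre <- pre[order(key(pre)), , drop = FALSE]
  post <- post[order(key(post)), , drop = FALSE]
  if (!identical(key(pre), key(post)))
    stop("pre and post observations are not paired one-to-one", call. = FALSE)
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(unique(pre$case_id))),
                              unique(pre$case_id))
  gl <- unname(groups[pre$case_id])
  rows <- list()
  for (g in unique(gl)) {
    sel <- gl == g
    for (metric in c("WT", "TAT", "RT")) {
      a <- pre[[metric]][sel]; b <- post[[metric]][sel]
      d <- b - a
      drest <- (post[[metric]] - pre[[metric]])[!sel]
      p_sr <- if (all(d == 0)) 1 else
        suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
      p_rs <- if (length(drest))
        suppressWarnings(stats::wilcox.test(d, drest)$p.value) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        group = g, metric = metric, n = sum(sel),
        pre_median = stats::median(a), pre_iqr = .q75(a) - .q25(a),
        pre_mean = mean(a), pre_sd = stats::sd(a),
        pre_min = min(a), pre_max = max(a),
        post_median = stats::median(b), post_iqr = .q75(b) - .q25(b),
        post_mean = mean(b), post_sd = stats::sd(b),
        post_min = min(b), post_max = max(b),
        diff_median = stats::median(d), diff_iqr = .q75(d) - .q25(d),
        p_signed_rank = p_sr, p_rank_sum_vs_rest = p_rs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Load externally recorded per-case time data
#'
#' Reads a delimited file with columns `case_id, group, reader, session,
#' arm, WT, TAT, RT` (arm is `pre` or `post`) and returns paired pre/post
#' structures ready for [summarize_outcomes()].
#'
#' @param path CSV path.
#' @return list `pre`, `post` (aligned data frames).
#' @export
load_external_times <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "group", "reader", "session", "arm", "WT", "TAT", "RT")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (cc in c("WT", "TAT", "RT")) {
    if (!is.numeric(d[[cc]])) stop(cc, " must be numeric", call. = FALSE)
    if (any(!is.finite(d[[cc]])) || any(d[[cc]] < 0))
      stop(cc, " contains negative or non-finite values", call. = FALSE)
  }
  if (any(d$TAT < d$WT)) stop("TAT must be >= WT for every case", call. = FALSE)
  if (!all(d$arm %in% c("pre", "post")))
    stop("arm must be 'pre' or 'post'", call. = FALSE)
  pre <- d[d$arm == "pre", c("case_id", "reader", "WT", "TAT", "RT")]
  post <- d[d$arm == "post", c("case_id", "reader", "WT", "TAT", "RT")]
  kp <- paste(pre$case_id, pre$reader); kq <- paste(post$case_id, post$reader)
  if (!setequal(kp, kq) || length(kp) != length(kq))
    stop("pre/post observations do not pair one-to-one by case and reader",
         call. = FALSE)
  list(pre = pre, post = post)
}
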