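#' Greedy identity clustering of proteins
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted by
#' length (descending, ties by input order); each sequence joins the
#' first existing cluster whose representative aligns to it at global
#' identity >= `threshold` (identity excludes terminal-gap columns),
#' otherwise it founds a new cluster. Representatives are therefore
#' always the longest member of their cluster, and the clusters partition
#' the input.
#'
#' @param proteins an [Biostrings::AAStringSet] (or named character).
#' @param threshold identity threshold in `(0, 1]`; default 0.95, the
#'   screen's redundancy-collapse level.
#' @return A list with `clusters` (list of
#'   `list(representative_id, member_ids, threshold)`) and `map`
#'   (data.frame `member` -> `representative`).
#' @examples
#' p <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "MKLVINAAAA")
#' greedyCluster(p, threshold = 0.9)$map
#' @export
greedyCluster <- function(proteins, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    .stopf("threshold must be in (0, 1]")
  sqs <- .asRows(proteins)
  if (length(sqs) == 0L)
    return(list(clusters = list(),
                map = data.frame(member = character(),
                                 representative = character())))
  ids <- if (!is.null(names(sqs))) names(sqs) else
    paste0("seq", seq_along(sqs))
  ord <- order(-nchar(sqs), seq_along(sqs))
  reps <- integer()      # indices (into sqs) of cluster representatives
  members <- list()
  for (i in ord) {
    joined <- FALSE
    for (k in seq_along(reps)) {
      idv <- pairIdentity(sqs[reps[k]], sqs[i])
      if (!is.na(idv) && idv >= threshold) {
        members[[k]] <- c(members[[k]], i)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  clusters <- lapply(seq_along(reps), function(k)
    list(representative_id = ids[reps[k]],
         member_ids = ids[members[[k]]], threshold = threshold))
  map <- data.frame(
    member = unlist(lapply(clusters, `[[`, "member_ids")),
    representative = rep(vapply(clusters, `[[`, "", "representative_id"),
                         lengths(lapply(clusters, `[[`, "member_ids"))))
  list(clusters = clusters, map = map)
}
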