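#' Map monoisotopic masses onto pathway membership tables
#'
#' A pathway member is matched when any query neutral mass lies within
#' \code{tolerancePpm} of its monoisotopic mass. Coverage is the matched
#' fraction of the pathway's members; results are sorted by coverage
#' descending (ties by pathway id, so ordering is deterministic).
#'
#' @param masses Numeric vector of query neutral monoisotopic masses (Da),
#'   e.g. annotated metabolite masses. Matching is by neutral mass, not
#'   adduct m/z; convert observed m/z with \code{\link{neutralMass}} first.
#' @param pathways Pathway table (as from \code{\link{readPathwayTable}};
#'   defaults to the bundled miniature tables).
#' @param tolerancePpm Mass tolerance in ppm (default 2).
#' @return data.frame with one row per pathway: \code{pathway_id},
#'   \code{pathway_name}, \code{n_members}, \code{n_matched},
#'   \code{coverage}, and comma-separated \code{matched_members}.
#' @export
mapToPathways <- function(masses, pathways = pathwayLibrary(),
                          tolerancePpm = 2) {
  if (tolerancePpm <= 0) stop("tolerancePpm must be > 0", call. = FALSE)
  ids <- unique(pathways$pathway_id)
  res <- do.call(rbind, lapply(ids, function(pid) {
    members <- pathways[pathways$pathway_id == pid, , drop = FALSE]
    matched <- if (length(masses)) {
      vapply(members$monoisotopic_mass, function(m)
        any(abs(ppmError(masses, m)) <= tolerancePpm), TRUE)
    } else rep(FALSE, nrow(members))
    data.frame(pathway_id = pid, pathway_name = members$pathway_name[1],
               n_members = nrow(members), n_matched = sum(matched),
               coverage = sum(matched) / nrow(members),
               matched_members = paste(members$compound_id[matched],
                                       collapse = ","),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$coverage, res$pathway_id), ]
  rownames(res) <- NULL
  res
}

#' Pathway report for ubiquitous metabolites
#'
#' Joins the annotations of features flagged ubiquitous (equal abundance
#' across the two compared regions) to pathway coverage, and attaches
#' per-region mean TIC-normalized intensities for each matched member.
#'
#' @param statsTable Output of \code{\link{featureStatsTable}}.
#' @param annotations Output of \code{\link{annotateFeatures}} for the same
#'   feature centroids.
#' @param pathways Pathway table (default: bundled).
#' @param tolerancePpm Pathway mass tolerance in ppm (default 2).
#' @return List with \code{coverage} (per-pathway, as from
#'   \code{\link{mapToPathways}} restricted to ubiquitous annotations) and
#'   \code{members} (per matched member: pathway, compound, feature m/z and
#'   the per-region mean intensities).
#' @export
ubiquitousPathwayReport <- function(statsTable, annotations,
                                    pathways = pathwayLibrary(),
                                    tolerancePpm = 2) {
  ubiq <- statsTable[statsTable$ubiquitous, , drop = FALSE]
  ann <- annotations[annotations$feature_mz %in% ubiq$centroid_mz, ,
                     drop = FALSE]
  cov <- mapToPathways(ann$neutral_mass, pathways, tolerancePpm)
  members <- do.call(rbind, lapply(seq_len(nrow(pathways)), function(i) {
    hit <- which(abs(ppmError(ann$neutral_mass,
                              pathways$monoisotopic_mass[i])) <= tolerancePpm)
    if (!length(hit)) return(NULL)
    hit <- hit[1]
    st <- ubiq[match(ann$feature_mz[hit], ubiq$centroid_mz), , drop = FALSE]
    meanCols <- grep("^mean_", names(st), value = TRUE)
    data.frame(pathway_id = pathways$pathway_id[i],
               compound_id = pathways$compound_id[i],
               feature_mz = ann$feature_mz[hit],
               annotated_as = ann$compound_id[hit],
               st[meanCols], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  if (is.null(members))
    members <- data.frame(pathway_id = character(0),
                          compound_id = character(0),
                          feature_mz = numeric(0),
                          annotated_as = character(0))
  list(coverage = cov, members = members)
}
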