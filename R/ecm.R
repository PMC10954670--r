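# Tension-triggered ECM remodeling.
#
# ECM growth is downstream of cellular growth: new ECM nodes appear
# only where the chain is stretched beyond a strain threshold (which
# happens under the pressure of dividing cells), so cumulative ECM
# growth always lags the growth of the columnar layer.

#' Remodel an ECM chain
#'
#' For every chain segment whose strain `(L - L0) / L0` exceeds the
#' chain's tension threshold, one node is inserted at the segment
#' midpoint; the two child segments inherit half the parent rest length
#' each (total rest length is conserved) and the parent's stiffness.
#' Segments whose children would fall below `params$ecm$min_segment`
#' are not split further (ECM nodes have a finite size).
#' Bending triplets are re-derived around the new nodes with a straight
#' rest angle; existing triplets keep their rest angles.  Positions are
#' never changed, only connectivity and rest lengths, so the stretching
#' energy cannot increase at the insertion step.  At most one insertion
#' per segment per call.
#'
#' @param tis tissue.
#' @param chain_name `"columnar"` or `"squamous"`.
#' @param params parameter list.
#' @return updated tissue.
#' @export
remodel_ecm <- function(tis, chain_name, params) {
  chain_id <- which(names(tis$ecm) == chain_name)
  if (!length(chain_id)) stop("unknown ECM chain: ", chain_name)
  chain <- tis$ecm[[chain_id]]
  sp <- tis$springs
  rows <- which(sp$role == ROLE_ECM_SEGMENT & sp$chain == chain_id)
  if (!length(rows)) return(tis)
  L <- sqrt(rowSums((tis$pos[sp$j[rows], , drop = FALSE] -
                       tis$pos[sp$i[rows], , drop = FALSE])^2))
  strain <- (L - sp$L0[rows]) / sp$L0[rows]
  min_seg <- if (is.null(params$ecm$min_segment)) 0.1 else
    params$ecm$min_segment
  hot <- rows[strain > chain$tension_threshold &
                sp$L0[rows] / 2 >= min_seg]
  if (!length(hot)) return(tis)

  dmp <- tis$meta$params_damping
  nodes <- chain$nodes
  for (r in hot) {
    i <- sp$i[r]; j <- sp$j[r]
    mid <- (tis$pos[i, ] + tis$pos[j, ]) / 2
    res <- add_nodes(tis, matrix(mid, 1L, 2L), NODE_ECM,
                     damping = dmp$ecm)
    tis <- res$tis
    newid <- res$idx
    half <- sp$L0[r] / 2
    half_base <- sp$L0_base[r] / 2
    sp$j[r] <- newid; sp$L0[r] <- half; sp$L0_base[r] <- half_base
    sp <- rbind(sp, data.frame(
      i = newid, j = j, role = ROLE_ECM_SEGMENT,
      k_base = sp$k_base[r], k = sp$k[r],
      L0_base = half_base, L0 = half,
      active = TRUE, cell = NA_integer_, chain = chain_id))
    pos_in_chain <- match(i, nodes)
    nodes <- append(nodes, newid, after = pos_in_chain)
  }
  tis$springs <- sp
  tis$ecm[[chain_id]]$nodes <- nodes

  # rebuild bending triplets: keep rest angles of surviving middles,
  # straight rest angle for new middles
  bd <- tis$bends
  old <- bd[bd$chain == chain_id, , drop = FALSE]
  bd <- bd[is.na(bd$chain) | bd$chain != chain_id, , drop = FALSE]
  n <- length(nodes)
  if (n >= 3L) {
    a <- nodes[seq_len(n - 2L)]
    b <- nodes[seq_len(n - 2L) + 1L]
    c_ <- nodes[seq_len(n - 2L) + 2L]
    th0 <- rep(params$ecm$theta0, n - 2L)
    keep <- match(b, old$b)
    th0[!is.na(keep)] <- old$theta0[keep[!is.na(keep)]]
    kb <- rep(params$ecm$k_bend, n - 2L)
    kb[!is.na(keep)] <- old$k[keep[!is.na(keep)]]
    bd <- rbind(bd, data.frame(
      a = a, b = b, c = c_, form = FORM_COSINE,
      k_base = params$ecm$k_bend, k = kb, theta0 = th0,
      cell = NA_integer_, chain = chain_id))
  }
  tis$bends <- bd
  tis$excl <- NULL
  tis
}
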