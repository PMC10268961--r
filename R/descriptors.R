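## The 2D descriptor panel: ~58 descriptors spanning the seven families
## (partial charge, atom/bond counts, pharmacophore features, physical
## properties, subdivided surface areas, adjacency/distance indices,
## Kier-Hall connectivity). Open-source approximations grouped by family;
## no attempt to replicate any proprietary descriptor set numerically.

.ELEMENT_DATA <- local({
  sym <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
  data.frame(
    element = sym,
    Z = c(1, 5, 6, 7, 8, 9, 14, 15, 16, 17, 35, 53),
    Zv = c(1, 3, 4, 5, 6, 7, 4, 5, 6, 7, 7, 7),
    rvdw = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.10, 1.80, 1.80,
             1.75, 1.85, 1.98),
    row.names = sym)
})

.elemCol <- function(elems, col, default) {
  out <- .ELEMENT_DATA[elems, col]
  out[is.na(out)] <- default
  out
}

.PHARMACOPHORE_SMARTS <- list(
  phf_donor = "[#7!H0,#8!H0]",
  phf_acceptor_n = "[#7;X2,X3;!+]",
  phf_acceptor_o = "[#8;X1,X2;!+]",
  phf_aro6 = "a1aaaaa1",
  phf_aro5 = "a1aaaa1",
  phf_hydrophobe = "[CX4]",
  phf_cation = "[*+]",
  phf_anion = "[*-]",
  phf_base_n = "[NX3;H1,H2;!$(NC=O)]",
  phf_base_nplus = "[NX4+,NX3+]",
  phf_acid = "C(=O)[OX1H0-,OX2H1]"
)

#' The shipped descriptor-name to family map
#'
#' Reads inst/extdata/descriptor_families.csv once per session.
#'
#' @return named character vector descriptor -> family.
#' @export
descriptorFamilyMap <- function() {
  if (is.null(.familyCache$map)) {
    path <- system.file("extdata", "descriptor_families.csv",
                        package = "isescreen", mustWork = TRUE)
    df <- read.csv(path, stringsAsFactors = FALSE)
    .familyCache$map <- setNames(df$family, df$descriptor_name)
  }
  .familyCache$map
}
.familyCache <- new.env(parent = emptyenv())

# graph/charge descriptors for one molecule from its MOL2 (explicit H) parse
.graphDescriptors <- function(mol2) {
  at <- mol2$atoms; bd <- mol2$bonds
  heavy <- which(at$element != "H")
  hIdx <- which(at$element == "H")
  A <- length(heavy)
  out <- numeric(0)

  # H attached to each heavy atom; effective charge folds H charges in
  hOf <- integer(nrow(at))
  if (!is.null(bd)) for (r in seq_len(nrow(bd))) {
    a1 <- bd$a1[r]; a2 <- bd$a2[r]
    if (at$element[a1] == "H" && at$element[a2] != "H")
      hOf[a2] <- hOf[a2] + 1L
    if (at$element[a2] == "H" && at$element[a1] != "H")
      hOf[a1] <- hOf[a1] + 1L
  }
  q <- at$charge
  qEff <- q
  if (!is.null(bd) && length(hIdx)) for (r in seq_len(nrow(bd))) {
    a1 <- bd$a1[r]; a2 <- bd$a2[r]
    if (at$element[a1] == "H" && at$element[a2] != "H")
      qEff[a2] <- qEff[a2] + q[a1]
    if (at$element[a2] == "H" && at$element[a1] != "H")
      qEff[a1] <- qEff[a1] + q[a2]
  }

  # heavy-atom bond list
  hb <- NULL
  if (!is.null(bd)) {
    keep <- at$element[bd$a1] != "H" & at$element[bd$a2] != "H"
    hb <- bd[keep, , drop = FALSE]
  }
  B <- if (is.null(hb)) 0L else nrow(hb)
  elems <- at$element[heavy]
  pos <- match(seq_len(nrow(at)), heavy)  # atom index -> heavy rank
  deg <- integer(A)
  if (B) for (r in seq_len(B)) {
    deg[pos[hb$a1[r]]] <- deg[pos[hb$a1[r]]] + 1L
    deg[pos[hb$a2[r]]] <- deg[pos[hb$a2[r]]] + 1L
  }

  out["abc_atoms"] <- A
  out["abc_bonds"] <- B
  out["abc_carbons"] <- sum(elems == "C")
  out["abc_nitrogens"] <- sum(elems == "N")
  out["abc_oxygens"] <- sum(elems == "O")
  out["abc_sulfurs"] <- sum(elems == "S")
  out["abc_halogens"] <- sum(elems %in% c("F", "Cl", "Br", "I"))
  out["abc_double_bonds"] <- if (B) sum(hb$type == "2") else 0
  out["abc_triple_bonds"] <- if (B) sum(hb$type == "3") else 0
  out["abc_rings"] <- max(0L, B - A + 1L)

  out["pc_max"] <- max(q)
  out["pc_min"] <- min(q)
  out["pc_abs_sum"] <- sum(abs(q))
  pos_sum <- sum(q[q > 0]); neg_sum <- -sum(q[q < 0])
  out["pc_pos_sum"] <- pos_sum
  out["pc_neg_sum"] <- neg_sum
  out["pc_rel_pos"] <- if (pos_sum > 0) max(q) / pos_sum else 0
  out["pc_rel_neg"] <- if (neg_sum > 0) -min(q) / neg_sum else 0
  out["pc_sd"] <- if (length(q) > 1) sd(q) else 0

  # crude accessible-surface contribution per heavy atom, binned by charge
  rv <- .elemCol(elems, "rvdw", 1.7)
  surf <- 4 * pi * rv^2 * pmax(1 - 0.15 * deg, 0.25)
  qh <- qEff[heavy]
  cuts <- c(-Inf, -0.3, -0.15, -0.05, 0.05, 0.15, 0.3, Inf)
  bin <- findInterval(qh, cuts, rightmost.closed = TRUE)
  for (b in 1:7)
    out[paste0("vsa_q", b)] <- sum(surf[bin == b])
  out["vsa_polar"] <- sum(surf[elems %in% c("N", "O", "S", "P")])
  out["vsa_hydrophobic"] <- sum(surf[elems %in% c("C", "F", "Cl", "Br",
                                                  "I")])

  # Kier-Hall connectivity (simple and valence delta)
  hCount <- hOf[heavy]
  Zv <- .elemCol(elems, "Zv", 4)
  Z <- .elemCol(elems, "Z", 6)
  dv <- ifelse(Z <= 10, Zv - hCount,
               (Zv - hCount) / pmax(Z - Zv - 1, 1))
  dv <- pmax(dv, 1e-6)
  dOk <- deg > 0
  out["khc_chi0"] <- sum(1 / sqrt(deg[dOk]))
  out["khc_chi0v"] <- sum(1 / sqrt(dv[dOk]))
  chi1 <- chi1v <- 0
  if (B) for (r in seq_len(B)) {
    u <- pos[hb$a1[r]]; v <- pos[hb$a2[r]]
    chi1 <- chi1 + 1 / sqrt(deg[u] * deg[v])
    chi1v <- chi1v + 1 / sqrt(dv[u] * dv[v])
  }
  out["khc_chi1"] <- chi1
  out["khc_chi1v"] <- chi1v
  P1 <- B
  P2 <- sum(choose(deg, 2))
  out["khc_kappa1"] <- if (P1 > 0) A * (A - 1)^2 / P1^2 else 0
  out["khc_kappa2"] <- if (P2 > 0) (A - 1) * (A - 2)^2 / P2^2 else 0
  # paths of length 3: sum over edges of (d_u - 1)(d_v - 1) minus triangles
  P3 <- 0
  if (B && A >= 4) {
    adj <- matrix(0L, A, A)
    for (r in seq_len(B)) {
      u <- pos[hb$a1[r]]; v <- pos[hb$a2[r]]
      adj[u, v] <- 1L; adj[v, u] <- 1L
    }
    tri <- sum(diag(adj %*% adj %*% adj)) / 6
    for (r in seq_len(B)) {
      u <- pos[hb$a1[r]]; v <- pos[hb$a2[r]]
      P3 <- P3 + (deg[u] - 1) * (deg[v] - 1)
    }
    P3 <- P3 - 3 * tri
  }
  out["khc_kappa3"] <- if (P3 > 0) {
    if (A %% 2 == 1) (A - 1) * (A - 3)^2 / P3^2
    else (A - 3) * (A - 2)^2 / P3^2
  } else 0

  # adjacency / distance matrix indices
  if (B) {
    g <- igraph::make_graph(
      edges = rbind(pos[hb$a1], pos[hb$a2]), n = A, directed = FALSE)
    Dm <- igraph::distances(g)
    finite <- is.finite(Dm)
    Dm[!finite] <- 0
    wiener <- sum(Dm[upper.tri(Dm)])
    ecc <- apply(Dm, 1, max)
    dia <- max(ecc); rad <- min(ecc)
    s <- rowSums(Dm)
    Cnum <- max(0L, B - A + 1L)
    bj <- 0
    for (r in seq_len(B)) {
      u <- pos[hb$a1[r]]; v <- pos[hb$a2[r]]
      if (s[u] > 0 && s[v] > 0) bj <- bj + 1 / sqrt(s[u] * s[v])
    }
    out["adm_wiener"] <- wiener
    out["adm_balaban_j"] <- B / (Cnum + 1) * bj
    out["adm_diameter"] <- dia
    out["adm_radius"] <- rad
    out["adm_petitjean"] <- if (rad > 0) (dia - rad) / rad else 0
    out["adm_eccentric_conn"] <- sum(deg * ecc)
  } else {
    out[c("adm_wiener", "adm_balaban_j", "adm_diameter", "adm_radius",
          "adm_petitjean", "adm_eccentric_conn")] <- 0
  }
  out["adm_zagreb_m1"] <- sum(deg^2)
  out["adm_zagreb_m2"] <- if (B) {
    z <- 0
    for (r in seq_len(B))
      z <- z + deg[pos[hb$a1[r]]] * deg[pos[hb$a2[r]]]
    z
  } else 0
  out
}

#' Compute the 2D descriptor panel for standardized molecules
#'
#' One row per record; molecules for which any descriptor computation fails
#' are dropped and logged in the "rejected" attribute, never imputed. The
#' panel covers all seven descriptor families; the family map ships with
#' the package ([descriptorFamilyMap()]).
#'
#' @param records data.frame (id, smiles) of standardized molecules, or a
#'   character vector of SMILES.
#' @param descriptor_set panel name; "ise2d" is the shipped panel.
#' @return a [DescriptorTable-class] with attribute "rejected" (data.frame
#'   id, reason).
#' @export
computeDescriptors <- function(records, descriptor_set = "ise2d") {
  descriptor_set <- match.arg(descriptor_set, "ise2d")
  records <- .recordsFrame(records)
  n <- nrow(records)
  rejReason <- setNames(character(n), records$id)
  graphRows <- vector("list", n)
  for (i in seq_len(n)) {
    m2txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "MOL2", records$smiles[i],
                                options = data.frame(names = "h",
                                                     args = "")),
      error = function(e) "")
    mol2 <- .parseMol2(m2txt)
    if (is.null(mol2$atoms) || !nrow(mol2$atoms) ||
        anyNA(mol2$atoms$charge)) {
      rejReason[i] <- "MOL2 conversion failed"
      next
    }
    row <- tryCatch(.graphDescriptors(mol2), error = function(e) NULL)
    if (is.null(row) || anyNA(row)) {
      rejReason[i] <- "graph descriptor failure"
      next
    }
    graphRows[[i]] <- row
  }
  keep <- !nzchar(rejReason)
  kept <- records[keep, , drop = FALSE]
  if (!nrow(kept)) stop("descriptor computation failed for every molecule")

  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(kept$smiles))
  ChemmineR::cid(sdfs) <- kept$id
  prop <- ChemmineR::propOB(sdfs)
  smarts <- vapply(.PHARMACOPHORE_SMARTS, function(p)
    as.numeric(ChemmineR::smartsSearchOB(sdfs, p, uniqueMatches = TRUE)),
    numeric(nrow(kept)))
  if (nrow(kept) == 1) smarts <- matrix(smarts, nrow = 1,
                                        dimnames = list(NULL,
                                          names(.PHARMACOPHORE_SMARTS)))
  aro <- as.numeric(ChemmineR::smartsSearchOB(sdfs, "a",
                                              uniqueMatches = TRUE))
  rot <- as.numeric(ChemmineR::smartsSearchOB(
    sdfs, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE))

  gmat <- do.call(rbind, graphRows[keep])
  vals <- cbind(
    pp_MW = prop$MW, pp_logP = prop$logP, pp_TPSA = prop$TPSA,
    pp_MR = prop$MR, pp_HBA = prop$HBA2, pp_HBD = prop$HBD,
    gmat,
    abc_aromatic_atoms = aro, abc_rotatable = rot,
    phf_donor = smarts[, "phf_donor"],
    phf_acceptor = smarts[, "phf_acceptor_n"] + smarts[, "phf_acceptor_o"],
    phf_aromatic_rings = smarts[, "phf_aro6"] + smarts[, "phf_aro5"],
    phf_hydrophobe = smarts[, "phf_hydrophobe"],
    phf_cation = smarts[, "phf_cation"],
    phf_anion = smarts[, "phf_anion"],
    phf_basic_amine = smarts[, "phf_base_n"] + smarts[, "phf_base_nplus"],
    phf_carboxylic_acid = smarts[, "phf_acid"])
  rownames(vals) <- kept$id
  bad <- rowSums(is.na(vals)) > 0
  if (any(bad)) {
    rejReason[match(kept$id[bad], records$id)] <- "missing descriptor value"
    vals <- vals[!bad, , drop = FALSE]
  }
  if (!nrow(vals)) stop("descriptor computation failed for every molecule")
  fam <- descriptorFamilyMap()
  tab <- new("DescriptorTable", values = vals,
             family = fam[colnames(vals)])
  rej <- rejReason[nzchar(rejReason)]
  attr(tab, "rejected") <- data.frame(id = names(rej), reason = unname(rej),
                                      stringsAsFactors = FALSE)
  tab
}
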