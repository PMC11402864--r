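## Seeded generator of every pipeline input plus a ground-truth manifest.
## One integer seed drives all tables through a single RNG state, so a
## whole world is reproducible (byte-identical files), not just one file.

.SECTORS <- c("Toys and other children's products", "Furniture",
              "Packaging including food contact materials",
              "Electrical and electronic equipment", "Transport",
              "Personal care and household products", "Medical devices",
              "Building materials", "Synthetic textiles",
              "Agriculture, aquaculture and fisheries")

.DISEASE_CLASSES <- c("cancer", "respiratory system disease",
                      "reproductive system disease", "cognitive disorder",
                      "gastrointestinal system disease")

#' Configuration of a synthetic pipeline world
#'
#' Defines the size and planted structure of a generated world: number of
#' AOPs and the chain length (KEs per AOP), chemicals, defect rates for the
#' high-confidence filter (archived status, a KE titled "unknown", a
#' disconnected component, a missing MIE-to-AO path), the cytotoxicity
#' burst rate, and the target number of planted stressor-AOP links per
#' relevance level.
#'
#' @param seed integer seed driving every table.
#' @param n_aops number of AOPs in the release.
#' @param n_kes KEs per chain-structured AOP (chain length).
#' @param n_chemicals number of chemicals.
#' @param defect_rates named numeric in \[0,1\] over
#'   `c(archived, unknown_ke, disconnected, pathless)`; any positive rate is
#'   realized at least once.
#' @param burst_rate probability scale for planted cytotoxicity bursts
#'   (realized as `max(1, round(rate * n_chemicals))` pairs when positive).
#' @param planted_levels named integer vector `c(L1=, L2=, L3=, L4=, L5=)`
#'   of planted link counts per relevance level.
#' @param n_stressor_links number of AOP-Wiki-stressor-channel links to
#'   plant (each is a full-coverage Level-5 link).
#' @param burst_margin minimum distance of planted non-burst Z-scores from
#'   the +/-3 burst boundary.
#' @return a validated list of class `worldConfig`.
#' @export
worldConfig <- function(seed = 1L, n_aops = 12L, n_kes = 4L,
                        n_chemicals = 15L,
                        defect_rates = c(archived = 0.1, unknown_ke = 0.1,
                                         disconnected = 0.1,
                                         pathless = 0.1),
                        burst_rate = 0.1,
                        planted_levels = c(L1 = 3L, L2 = 2L, L3 = 2L,
                                           L4 = 1L, L5 = 2L),
                        n_stressor_links = 1L, burst_margin = 0.5) {
    cfg <- list(seed = as.integer(seed), n_aops = as.integer(n_aops),
                n_kes = as.integer(n_kes),
                n_chemicals = as.integer(n_chemicals),
                defect_rates = defect_rates, burst_rate = burst_rate,
                planted_levels = planted_levels,
                n_stressor_links = as.integer(n_stressor_links),
                burst_margin = burst_margin)
    class(cfg) <- "worldConfig"
    .validateWorldConfig(cfg)
    cfg
}

.defect_counts <- function(cfg) {
    r <- cfg$defect_rates
    need <- c("archived", "unknown_ke", "disconnected", "pathless")
    if (!all(need %in% names(r)))
        stop("defect_rates must name ", paste(need, collapse = ", "))
    vapply(r[need], function(p)
        if (p > 0) max(1L, as.integer(round(p * cfg$n_aops))) else 0L,
        integer(1))
}

.planted_counts <- function(cfg) {
    pl <- cfg$planted_levels
    need <- paste0("L", 1:5)
    if (!all(need %in% names(pl)))
        stop("planted_levels must name ", paste(need, collapse = ", "))
    vapply(pl[need], as.integer, integer(1))
}

.validateWorldConfig <- function(cfg) {
    if (any(cfg$defect_rates < 0 | cfg$defect_rates > 1))
        stop("defect_rates must be probabilities in [0, 1]")
    if (cfg$burst_rate < 0 || cfg$burst_rate > 1)
        stop("burst_rate must be in [0, 1]")
    if (cfg$n_aops < 1 || cfg$n_kes < 1 || cfg$n_chemicals < 1)
        stop("counts must be positive")
    pl <- .planted_counts(cfg)
    if (any(pl < 0)) stop("planted_levels must be non-negative")
    if (pl["L5"] > 0 && cfg$n_kes < 2)
        stop("planted Level-5 links need n_kes >= 2 ",
             "(an MIE and an AO on a directed path)")
    if ((pl["L2"] > 0 || pl["L3"] > 0) && cfg$n_kes < 2)
        stop("planted Level-2/3 links need n_kes >= 2")
    if (pl["L1"] > 0 && cfg$n_kes < 3)
        stop("planted Level-1 links need n_kes >= 3 ",
             "(an intermediate KE that is neither MIE nor AO)")
    nchem_link <- cfg$n_chemicals - cfg$n_stressor_links
    if (sum(pl) > 0 && nchem_link < 1)
        stop("not enough chemicals for planted links after reserving ",
             "stressor-channel chemicals")
    dc <- .defect_counts(cfg)
    n_l4 <- if (pl["L4"] > 0) ceiling(pl["L4"] / max(1, nchem_link)) else 0
    n_chain <- cfg$n_aops - sum(dc) - n_l4 - cfg$n_stressor_links
    if (sum(pl[c("L1", "L2", "L3", "L5")]) > 0 && n_chain < 1)
        stop("infeasible config: no chain AOP left for planted ",
             "Level-1/2/3/5 links (n_aops too small for the requested ",
             "defects and structures)")
    if (n_chain < 0 || (cfg$n_stressor_links > 0 && n_chain < 0))
        stop("infeasible config: n_aops smaller than requested defect ",
             "and structure counts")
    invisible(cfg)
}

.xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a synthetic world
#'
#' Writes a miniature AOP-Wiki-style XML release with planted defects,
#' assay hit tables with planted cytotoxicity bursts, CTD-like association
#' tables admitting known tetramers, curated mapping tables, a GO subset in
#' OBO format, sector/disease annotation tables, and a JSON ground-truth
#' manifest recording the planted rejections, bursts and stressor-AOP
#' links. Running [runPipeline()] on the world recovers the manifest
#' exactly.
#'
#' @param config a [worldConfig()].
#' @param dir output directory (created if needed).
#' @return a [SyntheticWorld-class].
#' @export
generateWorld <- function(config, dir) {
    stopifnot(inherits(config, "worldConfig"))
    .validateWorldConfig(config)
    set.seed(config$seed)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)

    dc <- .defect_counts(config)
    pl <- .planted_counts(config)
    nchem_link <- config$n_chemicals - config$n_stressor_links
    n_l4 <- if (pl["L4"] > 0) ceiling(pl["L4"] / max(1, nchem_link)) else 0L
    n_chain <- config$n_aops - sum(dc) - n_l4 - config$n_stressor_links

    ## --- chemicals -----------------------------------------------------
    cas <- sprintf("%d-%02d-%d", 100 + 7 * seq_len(config$n_chemicals),
                   (3 * seq_len(config$n_chemicals)) %% 90 + 10,
                   seq_len(config$n_chemicals) %% 10)
    link_chems <- cas[seq_len(nchem_link)]
    stressor_chems <- if (config$n_stressor_links > 0)
        cas[nchem_link + seq_len(config$n_stressor_links)] else character(0)

    ## --- AOP structures ------------------------------------------------
    structures <- c(rep("archived", dc["archived"]),
                    rep("unknown_ke", dc["unknown_ke"]),
                    rep("disconnected", dc["disconnected"]),
                    rep("pathless", dc["pathless"]),
                    rep("l4", n_l4),
                    rep("stressor", config$n_stressor_links),
                    rep("chain", n_chain))
    ## fixed assignment (not shuffled): acceptance must not depend on order
    ke_rows <- list(); ker_rows <- list(); aop_rows <- list()
    ke_counter <- 0L; ker_counter <- 0L
    newKe <- function(title, level) {
        ke_counter <<- ke_counter + 1L
        ke_rows[[ke_counter]] <<- data.frame(
            id = ke_counter, title = title, level = level,
            go = sprintf("GO:%07d", ke_counter),
            stringsAsFactors = FALSE)
        ke_counter
    }
    woe_cycle <- c("High", "High", "Moderate", "Low")
    newKer <- function(up, down) {
        ker_counter <<- ker_counter + 1L
        ker_rows[[ker_counter]] <<- data.frame(
            id = ker_counter, up = up, down = down,
            adjacency = "adjacent",
            woe = woe_cycle[(ker_counter - 1L) %% 4L + 1L],
            stringsAsFactors = FALSE)
        ker_counter
    }
    for (i in seq_along(structures)) {
        st <- structures[i]
        if (st == "l4") {
            m1 <- newKe(sprintf("Activation, receptor %d", i), "molecular")
            m2 <- newKe(sprintf("Activation, enzyme %d", i), "molecular")
            k  <- newKe(sprintf("Increase, oxidative stress %d", i),
                        "cellular")
            a1 <- newKe(sprintf("Organ dysfunction %d", i), "individual")
            a2 <- newKe(sprintf("Decrease, growth %d", i), "individual")
            kers <- c(newKer(m1, k), newKer(m2, k), newKer(k, a1),
                      newKer(m1, a2))
            aop_rows[[i]] <- list(id = i, structure = st,
                                  kes = c(m1, m2, k, a1, a2),
                                  mies = c(m1, m2), aos = c(a1, a2),
                                  kers = kers, status = "active",
                                  l4_pair = c(m2, a2))
        } else {
            m <- config$n_kes
            ids <- integer(m)
            for (j in seq_len(m)) {
                lvl <- if (j == 1) "molecular" else if (j == m)
                    "individual" else "cellular"
                ttl <- if (st == "unknown_ke" && j == 2 && m >= 2)
                    "Unknown" else
                    sprintf("Key event %d of pathway %d", j, i)
                ids[j] <- newKe(ttl, lvl)
            }
            if (st == "pathless") {
                kers <- vapply(seq_len(m - 1), function(j)
                    newKer(ids[j + 1], ids[j]), integer(1))
            } else {
                kers <- vapply(seq_len(m - 1), function(j)
                    newKer(ids[j], ids[j + 1]), integer(1))
            }
            kes <- ids
            if (st == "disconnected")
                kes <- c(kes, newKe(sprintf("Isolated event %d", i),
                                    "cellular"))
            aop_rows[[i]] <- list(
                id = i, structure = st, kes = kes, mies = ids[1],
                aos = ids[m], kers = kers,
                status = if (st == "archived") "archived" else "active")
        }
    }
    ke_df <- do.call(rbind, ke_rows)
    ker_df <- do.call(rbind, ker_rows)

    ## --- planted rejections -------------------------------------------
    reason_of <- c(archived = "archived", unknown_ke = "unknown_ke_title",
                   disconnected = "disconnected",
                   pathless = "no_mie_ao_path")
    rejections <- do.call(rbind, lapply(aop_rows, function(a)
        if (a$structure %in% names(reason_of)) data.frame(
            aop_id = paste0("AOP:", a$id),
            reason = unname(reason_of[a$structure]),
            stringsAsFactors = FALSE) else NULL))
    if (is.null(rejections))
        rejections <- data.frame(aop_id = character(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE)

    ## --- planted links -------------------------------------------------
    chain_aops <- Filter(function(a) a$structure == "chain", aop_rows)
    l4_aops <- Filter(function(a) a$structure == "l4", aop_rows)
    stressor_aops <- Filter(function(a) a$structure == "stressor", aop_rows)
    used_pairs <- character(0)
    links <- list(); assoc_plan <- list()
    planOne <- function(level, aop, chem) {
        kes <- aop$kes
        picked <- switch(as.character(level),
            "1" = kes[2],                      # intermediate only
            "2" = aop$aos[1],
            "3" = aop$mies[1],
            "4" = aop$l4_pair,
            "5" = c(aop$mies[1], aop$aos[1]))
        links[[length(links) + 1L]] <<- data.frame(
            chemical = chem, aop_id = paste0("AOP:", aop$id),
            level = as.integer(level),
            coverage = length(picked) / length(kes),
            stringsAsFactors = FALSE)
        for (k in picked)
            assoc_plan[[length(assoc_plan) + 1L]] <<- list(
                chemical = chem, ke = k)
    }
    for (level in c(1L, 2L, 3L, 4L, 5L)) {
        cnt <- pl[paste0("L", level)]
        if (cnt == 0) next
        pool <- if (level == 4L) l4_aops else chain_aops
        for (j in seq_len(cnt)) {
            aop <- pool[[(j - 1L) %% length(pool) + 1L]]
            chem <- NULL
            for (ci in seq_along(link_chems)) {
                cand <- link_chems[(j + ci - 2L) %% length(link_chems) + 1L]
                key <- paste(cand, aop$id)
                if (!(key %in% used_pairs)) { chem <- cand; break }
            }
            if (is.null(chem))
                stop("infeasible config: cannot place planted Level-",
                     level, " link ", j, " without duplicating a ",
                     "(chemical, AOP) pair; increase n_chemicals or n_aops")
            used_pairs <- c(used_pairs, paste(chem, aop$id))
            planOne(level, aop, chem)
        }
    }
    for (j in seq_along(stressor_aops)) {
        aop <- stressor_aops[[j]]
        links[[length(links) + 1L]] <- data.frame(
            chemical = stressor_chems[j], aop_id = paste0("AOP:", aop$id),
            level = 5L, coverage = 1, stringsAsFactors = FALSE)
    }
    link_df <- if (length(links)) do.call(rbind, links) else
        data.frame(chemical = character(0), aop_id = character(0),
                   level = integer(0), coverage = numeric(0),
                   stringsAsFactors = FALSE)
    link_df <- link_df[order(link_df$chemical, link_df$aop_id), ,
                       drop = FALSE]
    rownames(link_df) <- NULL

    ## --- route planted associations over the five channels -------------
    channels <- c("toxcast", "ctd_phenotype", "ctd_disease", "deduct",
                  "neurotoxkb")
    chan_i <- 0L
    route <- function(ke_level) {
        repeat {
            chan_i <<- chan_i + 1L
            ch <- channels[(chan_i - 1L) %% 5L + 1L]
            if (ch != "toxcast" || ke_level %in% c("molecular", "cellular"))
                return(ch)
        }
    }
    ## one chemical gets an old CAS alias used throughout the input tables
    alias_map <- data.frame(old = character(0), new = character(0),
                            stringsAsFactors = FALSE)
    if (nrow(link_df)) {
        aliased <- link_df$chemical[1]
        alias_map <- data.frame(old = paste0("OLD-", aliased),
                                new = aliased, stringsAsFactors = FALSE)
    }
    as_input_cas <- function(chem)
        if (nrow(alias_map) && chem == alias_map$new) alias_map$old else chem

    hits <- list(); ep_genes <- list(); ke_genes <- list(); wl <- list()
    ep_ann <- list()
    cg <- list(); cp <- list(); cd <- list(); gd <- list()
    phen_wl <- list(); dis_map <- list()
    obo_children <- list()    # child GO term -> parent (a KE process term)
    dummy_go <- character(0)
    deduct <- list(); deduct_map <- list()
    ntx <- list(); ntx_map <- list()
    gmad <- 0.25
    cyto_median <- stats::setNames(round(stats::runif(
        config$n_chemicals, 0.5, 2.5), 4), cas)
    ep_counter <- 0L; aux_counter <- 0L
    zsign <- 1
    addToxcast <- function(chem, keId) {
        ep_counter <<- ep_counter + 1L
        ep <- sprintf("AEID_%04d", ep_counter)
        gene <- sprintf("TCG%04d", ep_counter)
        ep_genes[[length(ep_genes) + 1L]] <<- data.frame(
            endpoint_id = ep, gene = gene, stringsAsFactors = FALSE)
        ep_ann[[length(ep_ann) + 1L]] <<- data.frame(
            endpoint_id = ep, name = paste0("assay endpoint ", ep),
            description = "synthetic reporter assay",
            stringsAsFactors = FALSE)
        ke_genes[[length(ke_genes) + 1L]] <<- data.frame(
            ke_id = paste0("KE:", keId), gene = gene,
            stringsAsFactors = FALSE)
        wl[[length(wl) + 1L]] <<- data.frame(
            endpoint_id = ep, ke_id = paste0("KE:", keId),
            stringsAsFactors = FALSE)
        z <- zsign * (3 + config$burst_margin + stats::runif(1, 0, 1.5))
        zsign <<- -zsign
        hits[[length(hits) + 1L]] <<- data.frame(
            chemical = as_input_cas(chem), endpoint_id = ep, hitc = 1,
            top = if (z > 0) 2.1 else -1.3,
            neg_log_ac50 = round(cyto_median[[chem]] + z * gmad, 6),
            stringsAsFactors = FALSE)
        ep
    }
    addCtdPhen <- function(chem, keId) {
        aux_counter <<- aux_counter + 1L
        ke_go <- ke_df$go[ke_df$id == keId]
        ## alternate direct match and match-via-parent-expansion
        if (aux_counter %% 2L == 0L) {
            phen <- sprintf("GO:%07d", 5e6 + aux_counter)
            obo_children[[phen]] <<- ke_go
        } else phen <- ke_go
        g <- sprintf("CTDG%04d", aux_counter)
        d <- sprintf("MESH:P%04d", aux_counter)
        cg[[length(cg) + 1L]] <<- data.frame(
            chemical = as_input_cas(chem), gene = g, evidence = "curated",
            stringsAsFactors = FALSE)
        cp[[length(cp) + 1L]] <<- data.frame(
            chemical = as_input_cas(chem), phenotype = phen,
            evidence = "curated", stringsAsFactors = FALSE)
        cd[[length(cd) + 1L]] <<- data.frame(
            chemical = as_input_cas(chem), disease = d, evidence = "direct",
            stringsAsFactors = FALSE)
        gd[[length(gd) + 1L]] <<- data.frame(
            gene = g, disease = d, evidence = "direct",
            stringsAsFactors = FALSE)
        phen_wl[[length(phen_wl) + 1L]] <<- data.frame(
            phenotype = phen, ke_id = paste0("KE:", keId),
            stringsAsFactors = FALSE)
    }
    addCtdDis <- function(chem, keId) {
        aux_counter <<- aux_counter + 1L
        phen <- sprintf("GO:%07d", 6e6 + aux_counter)  # matches no KE
        dummy_go <<- c(dummy_go, phen)
        g <- sprintf("CTDG%04d", aux_counter)
        d <- sprintf("MESH:D%04d", aux_counter)
        cg[[length(cg) + 1L]] <<- data.frame(
            chemical = as_input_cas(chem), gene = g, evidence = "curated",
            stringsAsFactors = FALSE)
        cp[[length(cp) + 1L]] <<- data.frame(
            chemical = as_input_cas(chem), phenotype = phen,
            evidence = "curated", stringsAsFactors = FALSE)
        cd[[length(cd) + 1L]] <<- data.frame(
            chemical = as_input_cas(chem), disease = d, evidence = "direct",
            stringsAsFactors = FALSE)
        gd[[length(gd) + 1L]] <<- data.frame(
            gene = g, disease = d, evidence = "direct",
            stringsAsFactors = FALSE)
        dis_map[[length(dis_map) + 1L]] <<- data.frame(
            disease = d, ke_id = paste0("KE:", keId),
            stringsAsFactors = FALSE)
    }
    addCurated <- function(chem, keId, which) {
        aux_counter <<- aux_counter + 1L
        ep <- sprintf("%s endpoint %04d",
                      if (which == "deduct") "endocrine" else "neurotoxic",
                      aux_counter)
        row1 <- data.frame(chemical = as_input_cas(chem), endpoint = ep,
                           stringsAsFactors = FALSE)
        row2 <- data.frame(endpoint = ep, ke_id = paste0("KE:", keId),
                           stringsAsFactors = FALSE)
        if (which == "deduct") {
            deduct[[length(deduct) + 1L]] <<- row1
            deduct_map[[length(deduct_map) + 1L]] <<- row2
        } else {
            ntx[[length(ntx) + 1L]] <<- row1
            ntx_map[[length(ntx_map) + 1L]] <<- row2
        }
    }
    for (p in assoc_plan) {
        lvl <- ke_df$level[ke_df$id == p$ke]
        switch(route(lvl),
               toxcast = addToxcast(p$chemical, p$ke),
               ctd_phenotype = addCtdPhen(p$chemical, p$ke),
               ctd_disease = addCtdDis(p$chemical, p$ke),
               deduct = addCurated(p$chemical, p$ke, "deduct"),
               neurotoxkb = addCurated(p$chemical, p$ke, "neurotoxkb"))
    }

    ## --- planted bursts and negative controls --------------------------
    n_bursts <- if (config$burst_rate > 0)
        max(1L, as.integer(round(config$burst_rate * config$n_chemicals)))
        else 0L
    bursts <- list()
    accepted_chains <- c(chain_aops, stressor_aops)
    for (b in seq_len(n_bursts)) {
        chem <- cas[(b - 1L) %% config$n_chemicals + 1L]
        ## decoy KE: an accepted intermediate the chemical is not planted on
        mykes <- unlist(lapply(assoc_plan, function(p)
            if (p$chemical == chem) p$ke else NULL))
        decoy <- NULL
        for (a in accepted_chains) {
            candidates <- setdiff(a$kes[-c(1, length(a$kes))], mykes)
            if (length(candidates)) { decoy <- candidates[1]; break }
        }
        if (is.null(decoy)) next
        ep_counter <- ep_counter + 1L
        ep <- sprintf("AEID_%04d", ep_counter)
        gene <- sprintf("TCG%04d", ep_counter)
        ep_genes[[length(ep_genes) + 1L]] <- data.frame(
            endpoint_id = ep, gene = gene, stringsAsFactors = FALSE)
        ep_ann[[length(ep_ann) + 1L]] <- data.frame(
            endpoint_id = ep, name = paste0("assay endpoint ", ep),
            description = "synthetic reporter assay (burst decoy)",
            stringsAsFactors = FALSE)
        ke_genes[[length(ke_genes) + 1L]] <- data.frame(
            ke_id = paste0("KE:", decoy), gene = gene,
            stringsAsFactors = FALSE)
        wl[[length(wl) + 1L]] <- data.frame(
            endpoint_id = ep, ke_id = paste0("KE:", decoy),
            stringsAsFactors = FALSE)
        z <- round(stats::runif(1, -3 + config$burst_margin,
                                3 - config$burst_margin), 4)
        hits[[length(hits) + 1L]] <- data.frame(
            chemical = as_input_cas(chem), endpoint_id = ep, hitc = 0.95,
            top = 1.5,
            neg_log_ac50 = round(cyto_median[[chem]] + z * gmad, 6),
            stringsAsFactors = FALSE)
        bursts[[length(bursts) + 1L]] <- data.frame(
            chemical = chem, endpoint_id = ep, stringsAsFactors = FALSE)
    }
    burst_df <- if (length(bursts)) do.call(rbind, bursts) else
        data.frame(chemical = character(0), endpoint_id = character(0),
                   stringsAsFactors = FALSE)
    burst_df <- burst_df[order(burst_df$chemical, burst_df$endpoint_id), ,
                         drop = FALSE]
    rownames(burst_df) <- NULL
    ## an inactive hit exercising the hitc threshold (maps to nothing new)
    if (length(hits)) {
        first_ep <- hits[[1]]$endpoint_id
        hits[[length(hits) + 1L]] <- data.frame(
            chemical = cas[config$n_chemicals], endpoint_id = first_ep,
            hitc = 0.2, top = 0.4,
            neg_log_ac50 = round(cyto_median[[cas[config$n_chemicals]]] +
                                 4 * gmad, 6),
            stringsAsFactors = FALSE)
    }
    ## a CTD triple without the gene-disease link: yields no tetramer
    cg[[length(cg) + 1L]] <- data.frame(chemical = cas[1],
                                        gene = "CTDG9999",
                                        evidence = "curated",
                                        stringsAsFactors = FALSE)
    cp[[length(cp) + 1L]] <- data.frame(chemical = cas[1],
                                        phenotype = "GO:6999999",
                                        evidence = "curated",
                                        stringsAsFactors = FALSE)
    cd[[length(cd) + 1L]] <- data.frame(chemical = cas[1],
                                        disease = "MESH:D9999",
                                        evidence = "direct",
                                        stringsAsFactors = FALSE)
    dummy_go <- c(dummy_go, "GO:6999999")
    ## an unmapped curated endpoint (counter must tick, no association)
    deduct[[length(deduct) + 1L]] <- data.frame(
        chemical = cas[1], endpoint = "unmapped endocrine endpoint",
        stringsAsFactors = FALSE)

    ## --- write files ----------------------------------------------------
    p <- list()
    pth <- function(f) file.path(dir, f)
    bind <- function(lst, proto) if (length(lst))
        do.call(rbind, lst) else proto

    p$aopwiki_xml <- pth("aopwiki.xml")
    .writeWorldXml(p$aopwiki_xml, ke_df, ker_df, aop_rows, stressor_aops,
                   stressor_chems)

    hits_df <- bind(hits, data.frame(chemical = character(0),
                                     endpoint_id = character(0),
                                     hitc = numeric(0), top = numeric(0),
                                     neg_log_ac50 = numeric(0)))
    p$toxcast_hits <- pth("toxcast_hits.csv")
    utils::write.csv(hits_df, p$toxcast_hits, row.names = FALSE,
                     quote = FALSE)
    cyto_df <- data.frame(chemical = vapply(cas, as_input_cas,
                                            character(1),
                                            USE.NAMES = FALSE),
                          cytotox_median_log = unname(cyto_median),
                          global_mad = gmad, stringsAsFactors = FALSE)
    p$cytotox <- pth("cytotox.csv")
    utils::write.csv(cyto_df, p$cytotox, row.names = FALSE, quote = FALSE)
    p$assay_annotations <- pth("assay_annotations.tsv")
    writeTsv(bind(ep_ann, data.frame(endpoint_id = character(0),
                                     name = character(0),
                                     description = character(0))),
             p$assay_annotations)
    p$endpoint_genes <- pth("endpoint_genes.tsv")
    writeTsv(bind(ep_genes, data.frame(endpoint_id = character(0),
                                       gene = character(0))),
             p$endpoint_genes)
    p$ke_genes <- pth("ke_genes.tsv")
    writeTsv(bind(ke_genes, data.frame(ke_id = character(0),
                                       gene = character(0))), p$ke_genes)
    p$endpoint_ke_whitelist <- pth("endpoint_ke_whitelist.tsv")
    writeTsv(bind(wl, data.frame(endpoint_id = character(0),
                                 ke_id = character(0))),
             p$endpoint_ke_whitelist)
    proto_cg <- data.frame(chemical = character(0), gene = character(0),
                           evidence = character(0))
    p$ctd_cg <- pth("ctd_cg.tsv"); writeTsv(bind(cg, proto_cg), p$ctd_cg)
    p$ctd_cp <- pth("ctd_cp.tsv")
    writeTsv(bind(cp, data.frame(chemical = character(0),
                                 phenotype = character(0),
                                 evidence = character(0))), p$ctd_cp)
    p$ctd_cd <- pth("ctd_cd.tsv")
    writeTsv(bind(cd, data.frame(chemical = character(0),
                                 disease = character(0),
                                 evidence = character(0))), p$ctd_cd)
    p$ctd_gd <- pth("ctd_gd.tsv")
    writeTsv(bind(gd, data.frame(gene = character(0),
                                 disease = character(0),
                                 evidence = character(0))), p$ctd_gd)
    p$go_obo <- pth("go.obo")
    .writeWorldObo(p$go_obo, ke_df, obo_children, dummy_go)
    p$phenotype_whitelist <- pth("phenotype_whitelist.tsv")
    writeTsv(bind(phen_wl, data.frame(phenotype = character(0),
                                      ke_id = character(0))),
             p$phenotype_whitelist)
    p$disease_ke_map <- pth("disease_ke_map.tsv")
    writeTsv(bind(dis_map, data.frame(disease = character(0),
                                      ke_id = character(0))),
             p$disease_ke_map)
    p$deduct <- pth("deduct.tsv")
    writeTsv(bind(deduct, data.frame(chemical = character(0),
                                     endpoint = character(0))), p$deduct)
    p$deduct_ke_map <- pth("deduct_ke_map.tsv")
    writeTsv(bind(deduct_map, data.frame(endpoint = character(0),
                                         ke_id = character(0))),
             p$deduct_ke_map)
    p$neurotoxkb <- pth("neurotoxkb.tsv")
    writeTsv(bind(ntx, data.frame(chemical = character(0),
                                  endpoint = character(0))), p$neurotoxkb)
    p$neurotoxkb_ke_map <- pth("neurotoxkb_ke_map.tsv")
    writeTsv(bind(ntx_map, data.frame(endpoint = character(0),
                                      ke_id = character(0))),
             p$neurotoxkb_ke_map)
    p$cas_synonyms <- pth("cas_synonyms.tsv")
    writeTsv(alias_map, p$cas_synonyms)
    stressor_tbl <- data.frame(
        name = paste0("stressor of ", stressor_chems),
        chemical = stressor_chems, stringsAsFactors = FALSE)
    p$stressor_names <- pth("stressor_names.tsv")
    writeTsv(stressor_tbl, p$stressor_names)
    link_chem_all <- unique(link_df$chemical)
    sector_tbl <- if (length(link_chem_all)) data.frame(
        sector = .SECTORS[(seq_along(link_chem_all) - 1L) %% 10L + 1L],
        chemical = link_chem_all, stringsAsFactors = FALSE) else
        data.frame(sector = character(0), chemical = character(0),
                   stringsAsFactors = FALSE)
    p$sectors <- pth("sectors.tsv"); writeTsv(sector_tbl, p$sectors)
    acc_ids <- paste0("AOP:", vapply(
        c(chain_aops, l4_aops, stressor_aops), function(a) a$id,
        integer(1)))
    disease_tbl <- if (length(acc_ids)) data.frame(
        aop_id = acc_ids,
        disease_class = .DISEASE_CLASSES[(seq_along(acc_ids) - 1L) %% 5L
                                         + 1L],
        stringsAsFactors = FALSE) else
        data.frame(aop_id = character(0), disease_class = character(0),
                   stringsAsFactors = FALSE)
    p$disease_classes <- pth("disease_classes.tsv")
    writeTsv(disease_tbl, p$disease_classes)

    manifest <- list(rejections = rejections, bursts = burst_df,
                     links = link_df)
    p$manifest <- pth("manifest.json")
    jsonlite::write_json(manifest, p$manifest, dataframe = "columns",
                         digits = NA, pretty = TRUE)

    new("SyntheticWorld", dir = dir, paths = p, manifest = manifest,
        config = unclass(config))
}

.writeWorldXml <- function(path, ke_df, ker_df, aop_rows, stressor_aops,
                           stressor_chems) {
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<data xmlns="http://www.aopkb.org/aop-xml">')
    for (i in seq_len(nrow(ke_df))) {
        out <- c(out, sprintf('  <key-event id="%d">', ke_df$id[i]),
                 sprintf('    <title>%s</title>',
                         .xml_escape(ke_df$title[i])),
                 sprintf('    <biological-organization-level>%s</biological-organization-level>',
                         ke_df$level[i]),
                 '    <action>increased</action>',
                 sprintf('    <object-name>object %d</object-name>',
                         ke_df$id[i]),
                 sprintf('    <process-id>%s</process-id>', ke_df$go[i]),
                 '  </key-event>')
    }
    for (i in seq_len(nrow(ker_df))) {
        out <- c(out,
                 sprintf('  <key-event-relationship id="%d">',
                         ker_df$id[i]),
                 sprintf('    <upstream-id>%d</upstream-id>',
                         ker_df$up[i]),
                 sprintf('    <downstream-id>%d</downstream-id>',
                         ker_df$down[i]),
                 sprintf('    <adjacency>%s</adjacency>',
                         ker_df$adjacency[i]),
                 sprintf('    <evidence>%s</evidence>', ker_df$woe[i]),
                 '    <quantitative-understanding>Low</quantitative-understanding>',
                 '  </key-event-relationship>')
    }
    stressor_ids <- stats::setNames(seq_along(stressor_aops),
                                    vapply(stressor_aops,
                                           function(a) a$id, integer(1)))
    for (j in seq_along(stressor_aops)) {
        out <- c(out, sprintf('  <stressor id="%d">', j),
                 sprintf('    <name>%s</name>',
                         .xml_escape(paste0("stressor of ",
                                            stressor_chems[j]))),
                 '  </stressor>')
    }
    for (a in aop_rows) {
        out <- c(out, sprintf('  <aop id="%d">', a$id),
                 sprintf('    <title>Synthetic pathway %d (%s)</title>',
                         a$id, a$structure),
                 sprintf('    <saaop-status>%s</saaop-status>', a$status),
                 '    <oecd-status>Under Development</oecd-status>')
        for (m in a$mies)
            out <- c(out, sprintf(
                '    <molecular-initiating-event key-event-id="%d"/>', m))
        for (o in a$aos)
            out <- c(out, sprintf(
                '    <adverse-outcome key-event-id="%d"/>', o))
        out <- c(out, '    <key-events>')
        for (k in a$kes)
            out <- c(out, sprintf('      <key-event id="%d"/>', k))
        out <- c(out, '    </key-events>', '    <key-event-relationships>')
        for (k in a$kers)
            out <- c(out, sprintf('      <relationship id="%d"/>', k))
        out <- c(out, '    </key-event-relationships>')
        if (a$structure == "stressor") {
            sid <- stressor_ids[[as.character(a$id)]]
            out <- c(out, '    <aop-stressors>',
                     sprintf('      <aop-stressor stressor-id="%d"/>', sid),
                     '    </aop-stressors>')
        }
        out <- c(out, '    <applicability>',
                 '      <taxonomy name="Danio rerio" evidence="High"/>',
                 '      <sex name="mixed" evidence="Moderate"/>',
                 '    </applicability>', '  </aop>')
    }
    out <- c(out, '</data>')
    writeLines(out, path)
}

.writeWorldObo <- function(path, ke_df, obo_children, dummy_go) {
    root <- "GO:0008150"
    out <- c("format-version: 1.2", "ontology: go-synthetic-subset", "",
             "[Term]", paste0("id: ", root), "name: biological_process")
    for (i in seq_len(nrow(ke_df))) {
        out <- c(out, "", "[Term]", paste0("id: ", ke_df$go[i]),
                 paste0("name: process of ", ke_df$title[i]),
                 paste0("is_a: ", root, " ! biological_process"))
    }
    for (child in names(obo_children)) {
        out <- c(out, "", "[Term]", paste0("id: ", child),
                 paste0("name: child process ", child),
                 paste0("is_a: ", obo_children[[child]], " ! parent"))
    }
    for (d in unique(dummy_go)) {
        out <- c(out, "", "[Term]", paste0("id: ", d),
                 paste0("name: unrelated process ", d),
                 paste0("is_a: ", root, " ! biological_process"))
    }
    writeLines(out, path)
}
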