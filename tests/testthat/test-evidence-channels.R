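test_that("CAS canonicalization collapses synonyms and resolves chains", {
    map <- data.frame(old = c("A", "B"), new = c("B", "C"),
                      stringsAsFactors = FALSE)
    expect_equal(normalizeCas(c("A", "B"), map[1, ]), "B")
    expect_equal(normalizeCas("50-00-0", map), "50-00-0")  # pass-through
    expect_equal(normalizeCas("A", map), "C")              # transitive
    expect_equal(normalizeCas(c("A", "C", "A"), map, collapse = FALSE),
                 c("C", "C", "C"))
    cyc <- data.frame(old = c("A", "B"), new = c("B", "A"),
                      stringsAsFactors = FALSE)
    expect_error(normalizeCas("A", cyc), "cyclic")
})

test_that("hit-call filter is inclusive at the threshold and signs direction from top", {
    hits <- data.frame(
        chemical = paste0("c", 1:4), endpoint_id = paste0("e", 1:4),
        hitc = c(0.95, 0.89, 0.90, 1.0),
        top = c(2.1, 5.0, -1.0, NA), neg_log_ac50 = 1:4,
        stringsAsFactors = FALSE)
    expect_warning(act <- toxcastActive(hits), "unspecified")
    expect_equal(act$chemical, c("c1", "c3", "c4"))
    expect_equal(act$direction, c("activatory", "inhibitory",
                                  "unspecified"))
    expect_equal(suppressWarnings(
        toxcastActive(hits, hitcThreshold = 1))$chemical, "c4")
})

test_that("burst Z-score matches closed-form arithmetic with open bounds", {
    expect_equal(cytotoxBurstZ(0.5, 0.5, 0.25),
                 data.frame(z = 0, burst = TRUE))        # numerator zero
    r <- cytotoxBurstZ(1.5, 0.5, 0.25)
    expect_equal(r$z, 4)
    expect_false(r$burst)
    # z exactly -3 / +3 is NOT a burst ("lying between" read strictly)
    expect_false(cytotoxBurstZ(0.5 - 3 * 0.25, 0.5, 0.25)$burst)
    expect_false(cytotoxBurstZ(0.5 + 3 * 0.25, 0.5, 0.25)$burst)
    expect_true(cytotoxBurstZ(0.5 + 2.999 * 0.25, 0.5, 0.25)$burst)
    expect_error(cytotoxBurstZ(1, 0.5, 0), "positive")
    expect_error(cytotoxBurstZ(1, 0.5, -1), "positive")
    # a chemical without a cytotoxicity profile is kept, with a warning
    expect_warning(r <- cytotoxBurstZ(c(1, 2), c(0.5, NA), 0.25),
                   "without a")
    expect_equal(r$burst, c(TRUE, FALSE))
})

test_that("Z-score is location and scale invariant", {
    set.seed(9)
    for (i in 1:50) {
        x <- stats::runif(1, -2, 4); med <- stats::runif(1, -1, 2)
        mad <- stats::runif(1, 0.05, 2)
        z0 <- cytotoxBurstZ(x, med, mad)$z
        shift <- stats::runif(1, -5, 5)
        expect_equal(cytotoxBurstZ(x + shift, med + shift, mad)$z, z0)
        c_ <- stats::runif(1, 0.1, 4)
        expect_equal(cytotoxBurstZ(med + c_ * (x - med), med,
                                   c_ * mad)$z, z0)
    }
})

test_that("gene-overlap endpoint-KE candidates equal the pairwise-intersection oracle", {
    eg <- data.frame(endpoint_id = c("e1", "e1", "e2", "e3"),
                     gene = c("ESR1", "TP53", "esr1", "BRCA1"),
                     stringsAsFactors = FALSE)
    kg <- data.frame(ke_id = c("KE:1", "KE:1", "KE:2"),
                     gene = c("ESR1", "ESR2", "TP53"),
                     stringsAsFactors = FALSE)
    expect_warning(cand <- mapEndpointsToKes(eg, kg), "whitelist")
    # brute force over all (endpoint, KE) pairs, case-insensitive
    oracle <- list()
    for (e in unique(eg$endpoint_id)) for (k in unique(kg$ke_id)) {
        if (length(intersect(toupper(eg$gene[eg$endpoint_id == e]),
                             toupper(kg$gene[kg$ke_id == k]))))
            oracle[[length(oracle) + 1L]] <- data.frame(
                endpoint_id = e, ke_id = k, stringsAsFactors = FALSE)
    }
    oracle <- do.call(rbind, oracle)
    oracle <- oracle[order(oracle$endpoint_id, oracle$ke_id), ]
    rownames(oracle) <- NULL
    expect_equal(cand, oracle)
    # whitelist restricts; disjoint gene sets never pair
    wl <- data.frame(endpoint_id = "e1", ke_id = "KE:2",
                     stringsAsFactors = FALSE)
    expect_equal(mapEndpointsToKes(eg, kg, wl)$endpoint_id, "e1")
    expect_false("e3" %in% cand$endpoint_id)
})

test_that("KE-gene annotations outside molecular/cellular levels are ineligible", {
    eg <- data.frame(endpoint_id = "e1", gene = "G1",
                     stringsAsFactors = FALSE)
    kg <- data.frame(ke_id = c("KE:1", "KE:2"), gene = c("G1", "G1"),
                     stringsAsFactors = FALSE)
    lv <- data.frame(ke_id = c("KE:1", "KE:2"),
                     biological_level = c("molecular", "individual"),
                     stringsAsFactors = FALSE)
    cand <- suppressWarnings(mapEndpointsToKes(eg, kg, keLevels = lv))
    expect_equal(cand$ke_id, "KE:1")
})

test_that("CGPD tetramer join equals the four-way nested-loop oracle", {
    one <- function(chem, gene, phen, dis) list(
        cg = data.frame(chemical = chem, gene = gene,
                        evidence = "curated", stringsAsFactors = FALSE),
        cp = data.frame(chemical = chem, phenotype = phen,
                        evidence = "curated", stringsAsFactors = FALSE),
        cd = data.frame(chemical = chem, disease = dis,
                        evidence = "direct", stringsAsFactors = FALSE),
        gd = data.frame(gene = gene, disease = dis,
                        evidence = "direct", stringsAsFactors = FALSE))
    t1 <- one("c1", "g1", "p1", "d1")
    expect_equal(nrow(buildCgpdTetramers(t1$cg, t1$cp, t1$cd, t1$gd)), 1)
    # removing the gene-disease link kills the tetramer
    expect_equal(nrow(buildCgpdTetramers(
        t1$cg, t1$cp, t1$cd, t1$gd[0, ])), 0)
    expect_error(buildCgpdTetramers(t1$cg[, 1:2], t1$cp, t1$cd, t1$gd),
                 "evidence")

    set.seed(31)
    for (i in 1:20) {
        rand_tab <- function(cols, ev_vals) {
            n <- sample(3:10, 1)
            df <- data.frame(a = sample(paste0(cols[1], 1:4), n, TRUE),
                             b = sample(paste0(cols[2], 1:4), n, TRUE),
                             evidence = sample(ev_vals, n, TRUE),
                             stringsAsFactors = FALSE)
            names(df)[1:2] <- cols
            df
        }
        cg <- rand_tab(c("chemical", "gene"), c("curated", "inferred"))
        cp <- rand_tab(c("chemical", "phenotype"),
                       c("curated", "inferred"))
        cd <- rand_tab(c("chemical", "disease"), c("direct", "marker"))
        gd <- rand_tab(c("gene", "disease"), c("direct", "marker"))
        expect_equal(buildCgpdTetramers(cg, cp, cd, gd),
                     oracle_tetramers(cg, cp, cd, gd), info = paste(i))
    }
})

test_that("GO neighbor expansion equals the explicit adjacency of a toy DAG", {
    obo <- c("format-version: 1.2", "",
             "[Term]", "id: GO:1", "name: root", "",
             "[Term]", "id: GO:2", "name: mid-a", "is_a: GO:1 ! root", "",
             "[Term]", "id: GO:3", "name: mid-b", "is_a: GO:1 ! root", "",
             "[Term]", "id: GO:4", "name: leaf-a", "is_a: GO:2 ! mid-a",
             "relationship: part_of GO:3 ! mid-b", "",
             "[Term]", "id: GO:5", "name: leaf-b", "is_a: GO:2 ! mid-a", "",
             "[Term]", "id: GO:6", "name: obsolete leaf",
             "is_a: GO:2 ! mid-a", "is_obsolete: true", "",
             "[Term]", "id: GO:7", "name: floater")
    f <- withr::local_tempfile(lines = obo, fileext = ".obo")
    onto <- parseObo(f)
    expect_setequal(onto$terms, paste0("GO:", c(1:5, 7)))  # obsolete gone
    nb <- expandGoNeighbors(paste0("GO:", c(1, 2, 4, 5, 7)), onto)
    expect_equal(nb[["GO:4"]], c("GO:2", "GO:3", "GO:4"))  # leaf + parents
    expect_equal(nb[["GO:1"]], c("GO:1", "GO:2", "GO:3"))  # root + children
    expect_equal(nb[["GO:2"]], c("GO:1", "GO:2", "GO:4", "GO:5"))
    expect_equal(nb[["GO:7"]], "GO:7")
    # part_of edges can be excluded
    onto2 <- parseObo(f, partOf = FALSE)
    expect_equal(expandGoNeighbors("GO:4", onto2)[["GO:4"]],
                 c("GO:2", "GO:4"))
    expect_warning(expandGoNeighbors("GO:99", onto), "absent")
    expect_equal(suppressWarnings(
        expandGoNeighbors("GO:99", onto))[["GO:99"]], "GO:99")
})

test_that("tetramer-to-KE mapping works directly and via neighbor expansion", {
    tet <- data.frame(chemical = c("c1", "c2", "c3"),
                      gene = "g", phenotype = c("GO:A", "GO:B", "GO:C"),
                      disease = c("D1", "D2", "D3"),
                      stringsAsFactors = FALSE)
    # GO:B's parent is GO:A, which is KE:1's process id
    goNb <- list("GO:A" = c("GO:A", "GO:root"),
                 "GO:B" = c("GO:A", "GO:B"), "GO:C" = "GO:C")
    keProc <- data.frame(ke_id = "KE:1", process_id = "GO:A",
                         stringsAsFactors = FALSE)
    wl <- data.frame(phenotype = c("GO:A", "GO:B"),
                     ke_id = c("KE:1", "KE:1"), stringsAsFactors = FALSE)
    dmap <- data.frame(disease = "D3", ke_id = "KE:9",
                       stringsAsFactors = FALSE)
    assoc <- mapCtdToKes(tet, goNb, keProc, wl, dmap)
    phen <- assoc[assoc$channel == "ctd_phenotype", ]
    expect_setequal(phen$chemical, c("c1", "c2"))  # c2 matches via parent
    expect_true(all(phen$ke_id == "KE:1"))
    dis <- assoc[assoc$channel == "ctd_disease", ]
    expect_equal(dis$chemical, "c3")
    expect_equal(dis$ke_id, "KE:9")
    # un-whitelisted phenotype never maps even if the GO term matches
    wl2 <- wl[wl$phenotype == "GO:B", ]
    assoc2 <- mapCtdToKes(tet, goNb, keProc, wl2, dmap)
    expect_setequal(assoc2$chemical[assoc2$channel == "ctd_phenotype"],
                    "c2")
    expect_warning(mapCtdToKes(tet, goNb, keProc, NULL, dmap),
                   "phenotype")
    expect_warning(mapCtdToKes(tet, goNb, keProc, wl, NULL), "disease")
})

test_that("curated endpoint channels join and count unmapped endpoints", {
    ce <- data.frame(chemical = c("c1", "c2", "c3"),
                     endpoint = c("reduced sperm count",
                                  "reduced sperm count", "novel endpoint"),
                     stringsAsFactors = FALSE)
    map <- data.frame(endpoint = "reduced sperm count", ke_id = "KE:5",
                      stringsAsFactors = FALSE)
    assoc <- suppressMessages(mapCuratedEndpoints(ce, map, "deduct"))
    expect_equal(nrow(assoc), 2)
    expect_true(all(assoc$channel == "deduct"))
    expect_equal(attr(assoc, "unmapped"), 1)
})

test_that("stressor channel expands every KE of a stressor's AOPs and deduplicates", {
    f1 <- chain_aop("AOP:1", paste0("KE:", 1:5))
    f2 <- chain_aop("AOP:2", paste0("KE:", c(5, 11, 12)))
    f1$aop$stressor_names <- list("bisphenol A")
    f2$aop$stressor_names <- list(c("bisphenol A", "mystery goo"))
    aopset <- bind_aopset(f1, f2)
    nm <- data.frame(name = "bisphenol A", chemical = "80-05-7",
                     stringsAsFactors = FALSE)
    assoc <- suppressMessages(aopwikiStressorChannel(aopset, nm))
    expect_equal(attr(assoc, "unresolved"), 1)
    # KE:5 shared: one pair, two evidence records
    expect_equal(sum(assoc$ke_id == "KE:5"), 2)
    expect_equal(nrow(associationPairs(assoc)), 7)
    expect_true(all(assoc$chemical == "80-05-7"))
})

test_that("channel merge is a union that only grows and never drops pairs", {
    a <- assoc_df("c1", "KE:1", "toxcast")
    b <- assoc_df("c1", "KE:1", "deduct")
    c_ <- assoc_df("c2", "KE:2", "neurotoxkb")
    m <- mergeChannels(list(a, b))
    expect_equal(nrow(m), 2)                       # two evidence records
    expect_equal(nrow(associationPairs(m)), 1)     # one pair
    expect_equal(nrow(mergeChannels(list())), 0)
    # adding a channel never removes a pair
    m2 <- mergeChannels(list(a, b, c_))
    expect_true(all(do.call(paste, associationPairs(m)) %in%
                    do.call(paste, associationPairs(m2))))
})

test_that("burst filtering only removes associations", {
    w <- generateWorld(worldConfig(seed = 21), withr::local_tempdir())
    p <- worldPaths(w)
    hits <- read.csv(p$toxcast_hits, colClasses = c(chemical = "character"))
    cyto <- read.csv(p$cytotox, colClasses = c(chemical = "character"))
    args <- list(hits = hits, cytotox = cyto,
                 endpointGenes = readTsv(p$endpoint_genes),
                 keGenes = readTsv(p$ke_genes),
                 whitelist = readTsv(p$endpoint_ke_whitelist))
    with_filter <- do.call(toxcastChannel, args)
    no_filter <- do.call(toxcastChannel,
                         c(args, list(burstBounds = c(-1e-9, 1e-9))))
    pf <- do.call(paste, associationPairs(with_filter$associations))
    pn <- do.call(paste, associationPairs(no_filter$associations))
    expect_true(all(pf %in% pn))
    expect_gt(length(pn), length(pf))  # the planted bursts came back
    expect_equal(nrow(no_filter$discardedBursts), 0)
})
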