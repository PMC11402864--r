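test_that("XML round-trip recovers AOP membership from a generated release", {
    w <- generateWorld(worldConfig(seed = 11, n_aops = 5,
                                   defect_rates = c(archived = 0,
                                                    unknown_ke = 0,
                                                    disconnected = 0,
                                                    pathless = 0),
                                   planted_levels = c(L1 = 1, L2 = 0,
                                                      L3 = 0, L4 = 0,
                                                      L5 = 1)),
                       dir = withr::local_tempdir())
    aopset <- parseAopWikiXml(worldPaths(w)$aopwiki_xml)
    ap <- aops(aopset)
    expect_equal(nrow(ap), 5)
    expect_equal(nrow(keyEvents(aopset)), 5 * 4)
    expect_equal(nrow(relationships(aopset)), 5 * 3)
    # chain structure: 4 KEs, first is MIE, last is AO, 3 KERs
    expect_true(all(lengths(ap$ke_ids) == 4))
    expect_true(all(lengths(ap$mie_ids) == 1))
    expect_true(all(lengths(ap$ao_ids) == 1))
    expect_true(all(lengths(ap$ker_ids) == 3))
    # KE metadata carried through
    ke <- keyEvents(aopset)
    expect_setequal(unique(ke$biological_level),
                    c("molecular", "cellular", "individual"))
    expect_true(all(lengths(ke$process_ids) == 1))
    # the stressor-structure AOP carries its stressor name
    named <- ap[lengths(ap$stressor_names) > 0, ]
    expect_equal(nrow(named), 1)
})

test_that("dangling references are quarantined with a warning, not dropped silently", {
    xml <- c('<?xml version="1.0"?>', "<data>",
             '<key-event id="1"><title>a</title></key-event>',
             '<key-event id="2"><title>b</title></key-event>',
             '<key-event-relationship id="1">',
             "<upstream-id>1</upstream-id>",
             "<downstream-id>2</downstream-id>",
             "</key-event-relationship>",
             '<key-event-relationship id="2">',
             "<upstream-id>2</upstream-id>",
             "<downstream-id>99</downstream-id>",
             "</key-event-relationship>",
             '<aop id="1"><title>t</title>',
             "<saaop-status>active</saaop-status>",
             '<molecular-initiating-event key-event-id="1"/>',
             '<adverse-outcome key-event-id="2"/>',
             '<key-events><key-event id="1"/><key-event id="2"/></key-events>',
             '<key-event-relationships><relationship id="1"/>',
             '<relationship id="2"/></key-event-relationships>',
             "</aop>", "</data>")
    f <- withr::local_tempfile(lines = xml, fileext = ".xml")
    expect_warning(aopset <- parseAopWikiXml(f), "quarantined")
    expect_equal(nrow(relationships(aopset)), 1)
    q <- quarantined(aopset)
    expect_true("KER:2" %in% q$context)       # dangling KER endpoint
    expect_true("AOP:1" %in% q$context)       # AOP referencing it
    expect_equal(aops(aopset)$ker_ids[[1]], "KER:1")
})

test_that("malformed XML names the problem instead of failing obscurely", {
    f <- withr::local_tempfile(lines = "<data><unclosed>", fileext = ".xml")
    expect_error(parseAopWikiXml(f), "malformed XML")
    expect_error(parseAopWikiXml(file.path(tempdir(), "nope.xml")),
                 "not found")
})

test_that("each filter rule fires with its own rejection reason, in order", {
    fixtures <- list(
        archived = chain_aop("AOP:1", paste0("KE:", 1:3), archived = TRUE),
        unknown = chain_aop("AOP:2", paste0("KE:", 11:13),
                            unknown_title = TRUE),
        disconnected = chain_aop("AOP:3", paste0("KE:", 21:23),
                                 extra_isolated_ke = "KE:24"),
        pathless = chain_aop("AOP:4", paste0("KE:", 31:33),
                             reversed = TRUE),
        good = chain_aop("AOP:5", paste0("KE:", 41:43)))
    aopset <- do.call(bind_aopset, unname(fixtures))
    fh <- filterHighConfidence(aopset)
    expect_equal(aops(fh$accepted)$aop_id, "AOP:5")
    rej <- fh$rejections
    expect_equal(rej$reason[match(paste0("AOP:", 1:4), rej$aop_id)],
                 c("archived", "unknown_ke_title", "disconnected",
                   "no_mie_ao_path"))
    # archived wins over any later defect: archived AND unknown-titled
    both <- chain_aop("AOP:9", paste0("KE:", 91:93), archived = TRUE,
                      unknown_title = TRUE)
    fh2 <- filterHighConfidence(bind_aopset(both))
    expect_equal(fh2$rejections$reason, "archived")
})

test_that("no_kes / no_kers / no_mie / no_ao rules fire on degenerate AOPs", {
    kes <- data.frame(ke_id = c("KE:1", "KE:2"),
                      title = c("a", "b"), stringsAsFactors = FALSE)
    kers <- data.frame(ker_id = "KER:1", upstream_ke = "KE:1",
                       downstream_ke = "KE:2", stringsAsFactors = FALSE)
    mk <- function(aop_id, ke, mie, ao, ker) {
        df <- data.frame(aop_id = aop_id, stringsAsFactors = FALSE)
        df$ke_ids <- list(ke); df$mie_ids <- list(mie)
        df$ao_ids <- list(ao); df$ker_ids <- list(ker)
        df
    }
    aopset <- makeAopSet(rbind(
        mk("AOP:1", character(0), character(0), character(0), character(0)),
        mk("AOP:2", c("KE:1", "KE:2"), "KE:1", "KE:2", character(0)),
        mk("AOP:3", c("KE:1", "KE:2"), character(0), "KE:2", "KER:1"),
        mk("AOP:4", c("KE:1", "KE:2"), "KE:1", character(0), "KER:1")),
        kes, kers)
    rej <- filterHighConfidence(aopset)$rejections
    expect_equal(rej$reason[match(paste0("AOP:", 1:4), rej$aop_id)],
                 c("no_kes", "no_kers", "no_mie", "no_ao"))
})

test_that("'unknown' KE screening is whole-title and case-insensitive", {
    fix <- chain_aop("AOP:1", paste0("KE:", 1:3))
    fix$kes$title[2] <- "Unknown"
    expect_equal(filterHighConfidence(bind_aopset(fix))$rejections$reason,
                 "unknown_ke_title")
    fix$kes$title[2] <- "unknown protein binding"  # contains, not equals
    expect_equal(nrow(filterHighConfidence(
        bind_aopset(fix))$rejections), 0)
})

test_that("accepted/rejected partition is total and order-invariant", {
    w <- generateWorld(worldConfig(seed = 5), withr::local_tempdir())
    aopset <- parseAopWikiXml(worldPaths(w)$aopwiki_xml)
    fh <- filterHighConfidence(aopset)
    expect_equal(nrow(aops(fh$accepted)) + nrow(fh$rejections),
                 nrow(aops(aopset)))
    expect_equal(length(intersect(aops(fh$accepted)$aop_id,
                                  fh$rejections$aop_id)), 0)
    # permute input order; statuses and reasons must not move
    set.seed(42)
    perm <- sample(nrow(aops(aopset)))
    shuffled <- new("AopSet", aops = aops(aopset)[perm, ],
                    keyEvents = keyEvents(aopset),
                    relationships = relationships(aopset),
                    quarantined = quarantined(aopset))
    fh2 <- filterHighConfidence(shuffled)
    expect_setequal(aops(fh2$accepted)$aop_id, aops(fh$accepted)$aop_id)
    expect_equal(fh2$rejections, fh$rejections)
})

test_that("manual-curation overrides force acceptance and rejection", {
    fixtures <- bind_aopset(
        chain_aop("AOP:1", paste0("KE:", 1:3), archived = TRUE),
        chain_aop("AOP:2", paste0("KE:", 11:13)))
    ov <- data.frame(aop_id = c("AOP:1", "AOP:2"),
                     action = c("force_accept", "force_reject"),
                     note = c("expert review", "retracted evidence"),
                     stringsAsFactors = FALSE)
    fh <- filterHighConfidence(fixtures, overrides = ov)
    expect_equal(aops(fh$accepted)$aop_id, "AOP:1")
    expect_equal(fh$rejections$reason, "override")
    expect_equal(fh$rejections$detail, "retracted evidence")
})

test_that("MIE-to-AO path detection handles edge cases and cycles", {
    e <- function(up, down) data.frame(upstream_ke = up,
                                       downstream_ke = down,
                                       stringsAsFactors = FALSE)
    expect_true(hasMieAoPath("KE:1", "KE:2", e("KE:1", "KE:2")))
    expect_false(hasMieAoPath("KE:1", "KE:2",
                              e(character(0), character(0))))
    expect_false(hasMieAoPath(character(0), "KE:2", e("KE:1", "KE:2")))
    # 6-node graph with a cycle and a 3-hop route
    edges <- e(c("m", "a", "b", "c", "b", "x"),
               c("a", "b", "c", "a", "t", "m"))
    expect_true(hasMieAoPath("m", "t", edges))
    expect_true(oracle_path_exists("m", "t",
                                   data.frame(from = edges$upstream_ke,
                                              to = edges$downstream_ke)))
    # reachable only against edge direction
    expect_false(hasMieAoPath("t", "m", edges))
})

test_that("path detection agrees with exhaustive enumeration on random digraphs", {
    set.seed(101)
    for (i in 1:400) {
        g <- random_digraph(sample(2:10, 1), p_edge = stats::runif(1, .1, .4))
        if (!nrow(g$edges)) next
        mies <- sample(g$nodes, sample(1:2, 1))
        aos <- sample(g$nodes, sample(1:2, 1))
        kers <- data.frame(upstream_ke = g$edges$from,
                           downstream_ke = g$edges$to,
                           stringsAsFactors = FALSE)
        expect_equal(hasMieAoPath(mies, aos, kers),
                     oracle_path_exists(mies, aos, g$edges),
                     info = paste("case", i))
    }
})

test_that("adding KERs to an accepted AOP never destroys acceptance", {
    set.seed(77)
    base <- chain_aop("AOP:1", paste0("KE:", 1:4))
    for (rep in 1:20) {
        fix <- base
        pair <- sample(paste0("KE:", 1:4), 2)
        fix$kers <- rbind(fix$kers, data.frame(
            ker_id = "KER:extra", upstream_ke = pair[1],
            downstream_ke = pair[2], stringsAsFactors = FALSE))
        fix$aop$ker_ids <- list(c(fix$aop$ker_ids[[1]], "KER:extra"))
        expect_equal(nrow(filterHighConfidence(
            bind_aopset(fix))$rejections), 0)
    }
})
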