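# Visual-angle target assignment and the six attention measures.

simple_scene <- function() {
  dyad_scene(
    objects = data.frame(
      object_id = c("obj01", "obj02", "obj03"),
      kind = c("referent-candidate", "referent-candidate", "distractor"),
      x = c(0, 0.5, -0.5), y = c(0, 0, 0), z = c(1, 1, 1), radius = 0.1),
    persons = data.frame(role = c("instructor", "builder"),
                         x = 0, y = c(-1, 1), z = 1.5, radius = 0.15))
}

one_frame_stream <- function(direction, origin = c(0, -1, 1.5)) {
  gaze_stream(0, matrix(origin, 1), matrix(direction, 1), TRUE)
}

test_that("angular distance: aligned 0, orthogonal 90, random matches acos oracle", {
  expect_equal(angular_distance(c(0, 0, 0), c(0, 0, 1), c(0, 0, 5)), 0)
  expect_equal(angular_distance(c(0, 0, 0), c(1, 0, 0), c(0, 0, 3)), 90)
  set.seed(5)
  for (i in 1:50) {
    o <- rnorm(3); d <- rnorm(3); p <- rnorm(3, sd = 2)
    v <- p - o
    oracle <- acos(max(-1, min(1, sum(d * v) /
                                 (sqrt(sum(d^2)) * sqrt(sum(v^2)))))) * 180 / pi
    expect_equal(angular_distance(o, d, p), oracle, tolerance = 1e-9)
  }
  expect_error(angular_distance(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0)),
               "coincides")
})

test_that("frame target assignment: dead-ahead capture, nearest angle wins, none outside cone", {
  sc <- simple_scene()
  # instructor at (0,-1,1.5) looking at obj01 (0,0,1)
  dir_obj1 <- c(0, 1, -0.5)
  tg <- assign_targets(one_frame_stream(dir_obj1), sc, "instructor", 10)
  expect_equal(tg$target, "obj01")
  expect_equal(tg$angular_error_deg, 0, tolerance = 1e-9)

  # direction nudged a few degrees still captures the closest object
  tg2 <- assign_targets(one_frame_stream(dir_obj1 + c(0.05, 0, 0)), sc,
                        "instructor", 10)
  expect_equal(tg2$target, "obj01")

  # straight up: nothing within 10 degrees
  tg3 <- assign_targets(one_frame_stream(c(0, 0, 1)), sc, "instructor", 10)
  expect_equal(tg3$target, "none")

  # invalid frame -> none with NA angle
  g <- gaze_stream(0, matrix(c(0, -1, 1.5), 1), matrix(c(0, 1, -0.5), 1), FALSE)
  tg4 <- assign_targets(g, sc, "instructor", 10)
  expect_equal(tg4$target, "none")
  expect_true(is.na(tg4$angular_error_deg))
})

test_that("random scenes: winner equals exhaustive argmin with identical tie rules", {
  set.seed(13)
  for (i in 1:60) {
    n_obj <- sample(1:5, 1)
    objects <- data.frame(
      object_id = sprintf("obj%02d", seq_len(n_obj)),
      kind = "referent-candidate",
      x = runif(n_obj, -1, 1), y = runif(n_obj, -0.5, 0.5),
      z = runif(n_obj, 0.5, 1.5), radius = 0.1)
    sc <- dyad_scene(objects,
                     data.frame(role = c("instructor", "builder"),
                                x = 0, y = c(-2, 2), z = 1.5, radius = 0.15))
    o <- c(runif(1, -0.2, 0.2), -2, 1.5)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    thr <- runif(1, 5, 60)
    got <- assign_targets(gaze_stream(0, matrix(o, 1), matrix(d, 1), TRUE),
                          sc, "instructor", thr)$target
    cand <- rbind(objects[, c("object_id", "x", "y", "z")],
                  data.frame(object_id = "person", x = 0, y = 2, z = 1.5))
    names(cand)[1] <- "id"
    expect_equal(got, oracle_assign(o, d, cand, thr))
  }
})

test_that("exact angular ties break by distance then lexicographic id", {
  # two objects on the same ray: identical angle, different distance
  objects <- data.frame(object_id = c("far", "near"), kind = "distractor",
                        x = 0, y = c(0, -0.5), z = 1, radius = 0.1)
  sc <- dyad_scene(objects, data.frame(role = c("instructor", "builder"),
                                       x = 0, y = c(-2, 2), z = 1, radius = 0.15))
  tg <- assign_targets(one_frame_stream(c(0, 1, 0), origin = c(0, -2, 1)),
                       sc, "instructor", 10)
  expect_equal(tg$target, "near")

  # identical angle and distance -> lexicographically smaller id
  objects2 <- data.frame(object_id = c("b_obj", "a_obj"), kind = "distractor",
                         x = c(0.3, -0.3), y = 0, z = 1, radius = 0.1)
  sc2 <- dyad_scene(objects2, data.frame(role = c("instructor", "builder"),
                                         x = 0, y = c(-2, 2), z = 3, radius = 0.15))
  tg2 <- assign_targets(one_frame_stream(c(0, 1, 0), origin = c(0, -2, 1)),
                        sc2, "instructor", 45)
  expect_equal(tg2$target, "a_obj")
})

test_that("majority vote takes the maximal-proportion target, ignoring none frames", {
  seg <- list(start = 0, end = 1)
  tg <- make_targets(c(rep("objA", 30), rep("objB", 20)))
  expect_equal(majority_target(tg, seg), "objA")
  expect_equal(majority_target(make_targets(rep("none", 50)), seg), "none")
  set.seed(17)
  for (i in 1:40) {
    lab <- sample(c("a", "b", "c", "person", "none"), 60, replace = TRUE)
    tg <- make_targets(lab)
    votes <- table(lab[lab != "none"])
    oracle <- if (length(votes) == 0) "none" else
      names(votes)[order(-votes, names(votes))][1]
    expect_equal(majority_target(tg, list(start = 0, end = 1.2)), oracle)
  }
})

test_that("first-gaze latency counts from utterance onset at frame resolution", {
  seg <- list(start = 0, end = 2)
  expect_equal(first_gaze_latency(make_targets(c("obj01", rep("none", 10))),
                                  seg, "obj01"), 0.0)
  lab <- c(rep("objX", 25), rep("obj01", 25))
  expect_equal(first_gaze_latency(make_targets(lab), seg, "obj01"), 0.5)
  # never reached within the horizon -> undefined
  expect_true(is.na(first_gaze_latency(make_targets(rep("objX", 50)), seg,
                                       "obj01")))
  # reached after the segment but inside the extended horizon
  lab2 <- c(rep("objX", 60), rep("obj01", 20))
  expect_true(is.na(first_gaze_latency(make_targets(lab2),
                                       list(start = 0, end = 1), "obj01")))
  expect_equal(first_gaze_latency(make_targets(lab2),
                                  list(start = 0, end = 1), "obj01",
                                  horizon_end = 1.6), 1.2)
  # random sequences vs linear-scan oracle
  set.seed(19)
  for (i in 1:40) {
    lab <- sample(c("obj01", "objX", "none"), 80, replace = TRUE,
                  prob = c(0.2, 0.5, 0.3))
    got <- first_gaze_latency(make_targets(lab), list(start = 0, end = 1.6),
                              "obj01")
    hit <- which(lab == "obj01" & (seq_along(lab) - 1) / 50 < 1.6)
    oracle <- if (length(hit) == 0) NA_real_ else (hit[1] - 1) / 50
    expect_equal(got, oracle)
  }
})

test_that("gaze proportions are of segment time and conserve the unit total", {
  seg <- list(start = 0, end = 1)
  all_ref <- proportional_gaze(make_targets(rep("obj01", 50)), seg, "obj01")
  expect_equal(unlist(all_ref), c(gaze_to_target = 1, gaze_to_other = 0,
                                  gaze_to_person = 0))
  half <- proportional_gaze(make_targets(c(rep("objX", 25), rep("none", 25))),
                            seg, "obj01")
  expect_equal(unlist(half), c(gaze_to_target = 0, gaze_to_other = 0.5,
                               gaze_to_person = 0))
  expect_error(proportional_gaze(make_targets(rep("obj01", 10)),
                                 list(start = 5, end = 6), "obj01"),
               "no frames")
  set.seed(23)
  for (i in 1:40) {
    lab <- sample(c("obj01", "objX", "person", "none"), 60, replace = TRUE)
    p <- proportional_gaze(make_targets(lab), list(start = 0, end = 1.2), "obj01")
    expect_equal(p$gaze_to_target, mean(lab == "obj01"))
    expect_equal(p$gaze_to_other, mean(lab == "objX"))
    expect_equal(p$gaze_to_person, mean(lab == "person"))
    none_share <- mean(lab == "none")
    expect_equal(p$gaze_to_target + p$gaze_to_other + p$gaze_to_person +
                   none_share, 1)
  }
})

test_that("joint attention and mutual gaze are frame-wise AND counts, symmetric in roles", {
  seg <- list(start = 0, end = 1)
  both <- make_targets(rep("obj01", 50))
  expect_equal(joint_attention(both, both, seg, "obj01"), 1)
  a <- make_targets(c(rep("obj01", 25), rep("none", 25)))
  b <- make_targets(c(rep("none", 25), rep("obj01", 25)))
  expect_equal(joint_attention(a, b, seg, "obj01"), 0)   # temporally disjoint
  pp <- make_targets(rep("person", 50))
  oo <- make_targets(rep("obj01", 50))
  expect_equal(mutual_gaze(pp, pp, seg), 1)
  expect_equal(mutual_gaze(pp, oo, seg), 0)
  set.seed(29)
  for (i in 1:40) {
    la <- sample(c("obj01", "person", "none"), 50, replace = TRUE)
    lb <- sample(c("obj01", "person", "none"), 50, replace = TRUE)
    ta <- make_targets(la); tb <- make_targets(lb)
    expect_equal(joint_attention(ta, tb, seg, "obj01"),
                 mean(la == "obj01" & lb == "obj01"))
    expect_equal(mutual_gaze(ta, tb, seg),
                 mean(la == "person" & lb == "person"))
    expect_equal(joint_attention(ta, tb, seg, "obj01"),
                 joint_attention(tb, ta, seg, "obj01"))
    expect_equal(mutual_gaze(ta, tb, seg), mutual_gaze(tb, ta, seg))
  }
})

test_that("shrinking the capture cone never increases any gaze proportion", {
  gen <- generate_dyads(quiet_sim(), seed = 6)
  rec <- gen$recordings[[1]]
  seg <- rec$tier$segments[1, ]
  for (r in c("instructor", "builder")) {
    wide <- assign_targets(rec$gaze[[r]], rec$scene, r, 15)
    narrow <- assign_targets(rec$gaze[[r]], rec$scene, r, 5)
    pw <- proportional_gaze(wide, seg, seg$referent_id)
    pn <- proportional_gaze(narrow, seg, seg$referent_id)
    expect_lte(pn$gaze_to_target, pw$gaze_to_target)
    expect_lte(pn$gaze_to_other, pw$gaze_to_other)
    expect_lte(pn$gaze_to_person, pw$gaze_to_person)
  }
})
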