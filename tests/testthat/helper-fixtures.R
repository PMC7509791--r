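# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; heavy fixtures are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

test_geometry <- function(w = 60L, h = 40L) {
  # square pixels: 10 px per degree
  display_geometry(w, h, w / 10, h / 10)
}

rect_mask_matrix <- function(w, h, x0, x1, y0, y1) {
  m <- matrix(FALSE, h, w)
  m[(y0:y1) + 1L, (x0:x1) + 1L] <- TRUE
  m
}

# small hand-built catalog: 2 images x 3 objects, known labels
tiny_catalog <- function() {
  g <- test_geometry()
  objs <- list(
    scene_object("imgA", "o1", rect_mask_matrix(60, 40, 5, 14, 5, 14), "Face"),
    scene_object("imgA", "o2", rect_mask_matrix(60, 40, 30, 39, 5, 14), "Text"),
    scene_object("imgA", "o3", rect_mask_matrix(60, 40, 12, 21, 10, 19),
                 c("Taste", "Motion")),           # overlaps o1
    scene_object("imgB", "o1", rect_mask_matrix(60, 40, 5, 14, 20, 29), "Face"),
    scene_object("imgB", "o2", rect_mask_matrix(60, 40, 30, 39, 20, 29),
                 c("Text", "Smell")),
    scene_object("imgB", "o3", rect_mask_matrix(60, 40, 45, 54, 20, 29),
                 "Touched"))
  scene_catalog(g, objs, image_ids = c("imgA", "imgB"))
}

fix_row <- function(observer, image, x, y, onset, duration) {
  data.frame(observer_id = observer, image_id = image, x_px = x, y_px = y,
             onset_ms = onset, duration_ms = duration,
             stringsAsFactors = FALSE)
}

# ---- independent brute-force assignment oracle ---------------------------
# Containment: the pixel under round(x), round(y). Distance: minimum over
# EVERY true pixel of every mask (not just boundaries).
oracle_assign_ids <- function(x, y, masks, radius) {
  px <- round(x); py <- round(y)
  contains <- vapply(masks, function(m) {
    px >= 0 && px < ncol(m) && py >= 0 && py < nrow(m) && m[py + 1L, px + 1L]
  }, logical(1))
  if (any(contains)) return(which(contains))
  d <- vapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    sqrt(min((x - (idx[, 2L] - 1))^2 + (y - (idx[, 1L] - 1))^2))
  }, numeric(1))
  which(d <= radius)
}

random_mask_matrix <- function(w, h) {
  type <- sample(c("rect", "ellipse", "scatter", "pixel"), 1L)
  m <- matrix(FALSE, h, w)
  if (type == "rect") {
    x0 <- sample(0:(w - 2L), 1L); x1 <- sample(x0:(w - 1L), 1L)
    y0 <- sample(0:(h - 2L), 1L); y1 <- sample(y0:(h - 1L), 1L)
    m[(y0:y1) + 1L, (x0:x1) + 1L] <- TRUE
  } else if (type == "ellipse") {
    cx <- runif(1, 2, w - 3); cy <- runif(1, 2, h - 3)
    rx <- runif(1, 1, w / 3); ry <- runif(1, 1, h / 3)
    xs <- 0:(w - 1); ys <- 0:(h - 1)
    m <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`) <= 1
    if (!any(m)) m[round(cy) + 1L, round(cx) + 1L] <- TRUE
  } else if (type == "scatter") {
    m[sample.int(w * h, sample(3:25, 1L))] <- TRUE
  } else {
    m[sample.int(w * h, 1L)] <- TRUE
  }
  m
}

# ---- simulated study fixtures (cached; used by acceptance tests) ---------

std_catalog <- function(cfg, seed) {
  cached_fixture(paste0("catalog_", cfg$n_images, "_", seed),
                 function() generate_catalog(cfg, seed = seed))
}

# one scored synthetic session
scored_session <- function(cfg, catalog, obs_seed, sess_seed) {
  obs <- generate_observers(cfg, seed = obs_seed)
  fx <- simulate_session(obs, catalog, cfg, seed = sess_seed)
  score_gaze(fx, catalog)
}

# small scored synthetic study reused across consistency/selection tests
metrics_scores2 <- function() {
  cached_fixture("scores_small", function() {
    cfg <- sim_config(n_observers = 20L, n_images = 30L, seed = 42L)
    catl <- generate_catalog(cfg, seed = 101L)
    scored_session(cfg, catl, 102L, 103L)
  })
}
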