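# Small packaged Chinese medical word pools used by the synthetic-data
# generators.  Surface forms are synthesized compounds over these pools:
# realistic enough for segmentation and string-similarity behavior without
# shipping any scraped content.

.zh <- list(
  body = c("头", "胸", "腹", "腰", "背", "颈",
           "咽", "眼", "耳", "鼻", "口", "肩",
           "膝", "胃", "肝", "肺", "心", "肾",
           "脾", "肤"),
  sens1 = c("痛", "胀", "晕", "痒", "麻",
            "酸", "闷", "鸣"),
  sens2 = c("胀痛", "刺痛", "隐痛", "灼痛",
            "酸痛", "麻木", "肿胀", "瘙痒",
            "不适", "压痛"),
  adj = c("持续性", "阵发性", "间歇性",
          "进行性", "放射性", "弥漫性"),
  tcm_sym = c("阴虚", "阳虚", "气虚", "血虚",
              "气滞", "血瘀", "湿热", "痰湿",
              "盗汗", "畏寒", "乏力", "气短",
              "内热", "自汗", "怔忡", "健忘",
              "纳差", "便溏", "失眠", "多梦",
              "眩晕", "耳鸣", "腰酸", "膝软"),
  tcm_organ = c("肝", "脾", "肾", "心", "肺",
                "肝胆", "脾胃", "心脾", "肺肾", "肝肾"),
  disease_suffix = c("炎", "病", "综合征", "瘤"),
  med_prefix_w = c("阿莫", "布洛", "氯雷", "对乙",
                   "头孢", "左氧", "甲硝", "奥美"),
  med_prefix_t = c("银翘", "板蓝", "柴胡", "藿香",
                   "感冒", "止咳", "健脾", "安神"),
  med_suffix = c("片", "胶囊", "颗粒", "丸",
                 "口服液", "散"),
  departments = c("内科", "外科", "儿科", "妇科",
                  "神经内科", "皮肤科", "骨科",
                  "耳鼻喉科", "眼科", "呼吸内科"),
  tcm_departments = c("中医内科", "中医骨伤科",
                      "中医妇科", "针灸科"),
  exam_base = c("血常规", "尿常规", "心电图",
                "脑电图", "B超", "CT", "核磁共振",
                "肝功能", "血压", "体温"),
  noise_name = c("春季养生", "面部护理", "心理调适",
                 "减压方法", "美白技巧", "膳食搭配",
                 "瑜伽入门", "睡眠保健", "情绪管理",
                 "护肤常识"),
  noise_categories = c("养生", "美容", "心理"),
  han_pool = c("云", "山", "风", "林", "石", "水",
               "光", "星", "原", "泽")
)

.en_words <- c("fever", "cough", "headache", "pain", "chest", "nausea",
               "fatigue", "dizziness", "vomiting", "rash", "swelling",
               "itching", "chill", "sweating", "palpitation", "insomnia",
               "anorexia", "diarrhea", "constipation", "dyspnea",
               "acute", "chronic", "high", "mild", "severe", "persistent",
               "nocturnal", "recurrent", "abdominal", "lumbar")

# deterministic name builders -------------------------------------------------

synth_symptom_name <- function(n) {
  grid <- expand.grid(b = .zh$body, s = .zh$sens1, stringsAsFactors = FALSE)
  base <- paste0(grid$b, grid$s)
  if (n > length(base)) {
    grid2 <- expand.grid(a = .zh$adj, b = .zh$body, s = .zh$sens2,
                         stringsAsFactors = FALSE)
    base <- c(base, paste0(grid2$a, grid2$b, "部", grid2$s))
  }
  if (n > length(base)) stop("symptom name pool exhausted")
  sample(base, n)
}

synth_tcm_symptom_name <- function(n) {
  grid <- expand.grid(o = .zh$tcm_organ, s = .zh$tcm_sym,
                      stringsAsFactors = FALSE)
  base <- unique(c(.zh$tcm_sym, paste0(grid$o, grid$s)))
  if (n > length(base)) stop("TCM symptom name pool exhausted")
  sample(base, n)
}

synth_disease_name <- function(n) {
  grid <- expand.grid(b = .zh$body, s = .zh$disease_suffix,
                      stringsAsFactors = FALSE)
  base <- paste0(grid$b, grid$s)
  if (n > length(base)) stop("disease name pool exhausted")
  sample(base, n)
}

synth_medicine_name <- function(n, tcm = FALSE) {
  pre <- if (tcm) .zh$med_prefix_t else .zh$med_prefix_w
  grid <- expand.grid(p = pre, s = .zh$med_suffix, stringsAsFactors = FALSE)
  base <- paste0(grid$p, grid$s)
  if (n > length(base)) stop("medicine name pool exhausted")
  sample(base, n)
}

synth_department_name <- function(n, tcm_share = 0.3) {
  extra <- paste0(c("肝胆外", "胸外", "脑外", "泌尿外",
                    "消化内", "内分泌", "血液内",
                    "风湿免疫", "感染", "肿瘤",
                    "康复", "急诊", "老年病",
                    "新生儿", "生殖医学", "麻醉"), "科")
  pool <- c(.zh$departments, extra)
  if (n > length(pool) + length(.zh$tcm_departments))
    stop("department name pool exhausted")
  n_tcm <- min(length(.zh$tcm_departments), max(1L, floor(n * tcm_share)))
  c(sample(.zh$tcm_departments, n_tcm),
    sample(pool, n - n_tcm))
}

synth_examination_name <- function(n) {
  base <- c(paste0(.zh$exam_base, "检查"),
            paste0(.zh$body, "部影像检查"),
            paste0(.zh$body, "部超声检查"))
  if (n > length(base)) stop("examination name pool exhausted")
  sample(base, n)
}

# long compound symptom-complaint names for the fusion fixture (>= 10 chars,
# so a 2-character edit keeps name similarity comfortably high)
synth_long_name <- function(n) {
  grid <- expand.grid(a = .zh$adj, b1 = .zh$body, s1 = .zh$sens2,
                      b2 = .zh$body, s2 = .zh$sens2,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$b1 != grid$b2 & grid$s1 != grid$s2, ]
  base <- paste0(grid$a, grid$b1, "部", grid$s1, "伴有", grid$b2, "部", grid$s2)
  if (n > length(base)) stop("long name pool exhausted")
  sample(base, n)
}

# apply k random character edits (substitute / insert / delete)
perturb_name <- function(name, k) {
  chars <- strsplit(name, "", fixed = TRUE)[[1]]
  for (e in seq_len(k)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    pos <- sample(length(chars), 1L)
    repl <- sample(.zh$han_pool, 1L)
    if (op == "sub") chars[[pos]] <- repl
    else if (op == "ins") chars <- append(chars, repl, after = pos)
    else if (length(chars) > 2L) chars <- chars[-pos]
  }
  paste(chars, collapse = "")
}
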