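{
  "comment": "Catalog of the 13 optimal implant sites. Numbered sites (0-9) are the oblique implants defined by two projected angles; right side even, left side odd. Sagittal sites carry a tag and a single sagittal angle. 'frame' names the vertebra whose anatomical frame the projected angles use (transarticular implants project in the C1 frame). Shape kinds, default angles and canal_directed flags are package conventions for the generic centered-axis constructors and the synthetic scene generator; per-site surgical construction details are not part of this catalog.",
  "sites": [
    {"site": "c1_pedicle_right",          "id": 0,  "corridor": "C1 lateral mass (pedicular)", "laterality": "right",  "vertebra": "C1", "frame": "C1", "shape": "pyramid",        "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 35.0, "default_dorsal": 21.0},
    {"site": "c1_pedicle_left",           "id": 1,  "corridor": "C1 lateral mass (pedicular)", "laterality": "left",   "vertebra": "C1", "frame": "C1", "shape": "pyramid",        "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 35.0, "default_dorsal": -21.0},
    {"site": "transarticular_right",      "id": 2,  "corridor": "C1-C2 transarticular",        "laterality": "right",  "vertebra": "C1", "frame": "C1", "shape": "pyramid",        "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 26.0, "default_dorsal": 24.0},
    {"site": "transarticular_left",       "id": 3,  "corridor": "C1-C2 transarticular",        "laterality": "left",   "vertebra": "C1", "frame": "C1", "shape": "pyramid",        "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 26.0, "default_dorsal": -24.0},
    {"site": "c2_cranial_articular_right","id": 4,  "corridor": "C2 cranial articular surface","laterality": "right",  "vertebra": "C2", "frame": "C2", "shape": "hemi_ellipsoid", "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 42.0, "default_dorsal": 38.0},
    {"site": "c2_cranial_articular_left", "id": 5,  "corridor": "C2 cranial articular surface","laterality": "left",   "vertebra": "C2", "frame": "C2", "shape": "hemi_ellipsoid", "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 42.0, "default_dorsal": -38.0},
    {"site": "c2_pedicle_right",          "id": 6,  "corridor": "C2 pedicle",                  "laterality": "right",  "vertebra": "C2", "frame": "C2", "shape": "prism",          "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 31.0, "default_dorsal": 35.0},
    {"site": "c2_pedicle_left",           "id": 7,  "corridor": "C2 pedicle",                  "laterality": "left",   "vertebra": "C2", "frame": "C2", "shape": "prism",          "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 31.0, "default_dorsal": -35.0},
    {"site": "c2_caudal_body_right",      "id": 8,  "corridor": "C2 caudal vertebral body",    "laterality": "right",  "vertebra": "C2", "frame": "C2", "shape": "prism",          "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 15.0, "default_dorsal": 20.0},
    {"site": "c2_caudal_body_left",       "id": 9,  "corridor": "C2 caudal vertebral body",    "laterality": "left",   "vertebra": "C2", "frame": "C2", "shape": "prism",          "reported": ["sagittal", "dorsal"], "sagittal_site": false, "canal_directed": false, "default_sagittal": 15.0, "default_dorsal": -20.0},
    {"site": "c1_ventral_arch",           "id": null, "corridor": "C1 ventral arch",           "laterality": "midline","vertebra": "C1", "frame": "C1", "shape": "prism",          "reported": ["sagittal"],           "sagittal_site": true,  "canal_directed": true,  "default_sagittal": 20.0, "default_dorsal": 0.0},
    {"site": "c2_cranial_body",           "id": null, "corridor": "C2 cranial vertebral body", "laterality": "midline","vertebra": "C2", "frame": "C2", "shape": "pyramid",        "reported": ["sagittal"],           "sagittal_site": true,  "canal_directed": true,  "default_sagittal": 40.0, "default_dorsal": 0.0},
    {"site": "c2_caudal_body_mid",        "id": null, "corridor": "C2 caudal vertebral body",  "laterality": "midline","vertebra": "C2", "frame": "C2", "shape": "prism",          "reported": ["sagittal"],           "sagittal_site": true,  "canal_directed": false, "default_sagittal": 10.0, "default_dorsal": 0.0}
  ]
}
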