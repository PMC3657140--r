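# Modulatory model space: 21 patterns of emotion modulation over the six
# directed connections among FG, amygdala (AMY) and OFC, partitioned into
# 7 families.
#   Family 1: the six single-edge models (1-6)
#   Families 2-4: the three single bidirectional pairs (7-9)
#   Family 5: two-edge non-reciprocal patterns, both edges involving AMY (10-13)
#   Family 6: two-edge non-reciprocal patterns, one edge involving AMY (14-18)
#   Family 7: the three two-pair bidirectional models (19-21)
models:
  - {id: 1,  family: 1, edges: [[FG, AMY]]}
  - {id: 2,  family: 1, edges: [[FG, OFC]]}
  - {id: 3,  family: 1, edges: [[AMY, FG]]}
  - {id: 4,  family: 1, edges: [[AMY, OFC]]}
  - {id: 5,  family: 1, edges: [[OFC, FG]]}
  - {id: 6,  family: 1, edges: [[OFC, AMY]]}
  - {id: 7,  family: 2, edges: [[FG, AMY], [AMY, FG]]}
  - {id: 8,  family: 3, edges: [[FG, OFC], [OFC, FG]]}
  - {id: 9,  family: 4, edges: [[AMY, OFC], [OFC, AMY]]}
  - {id: 10, family: 5, edges: [[FG, AMY], [AMY, OFC]]}
  - {id: 11, family: 5, edges: [[FG, AMY], [OFC, AMY]]}
  - {id: 12, family: 5, edges: [[AMY, FG], [AMY, OFC]]}
  - {id: 13, family: 5, edges: [[AMY, FG], [OFC, AMY]]}
  - {id: 14, family: 6, edges: [[FG, AMY], [FG, OFC]]}
  - {id: 15, family: 6, edges: [[FG, AMY], [OFC, FG]]}
  - {id: 16, family: 6, edges: [[AMY, FG], [FG, OFC]]}
  - {id: 17, family: 6, edges: [[AMY, FG], [OFC, FG]]}
  - {id: 18, family: 6, edges: [[AMY, OFC], [FG, OFC]]}
  - {id: 19, family: 7, edges: [[FG, AMY], [AMY, FG], [FG, OFC], [OFC, FG]]}
  - {id: 20, family: 7, edges: [[FG, AMY], [AMY, FG], [AMY, OFC], [OFC, AMY]]}
  - {id: 21, family: 7, edges: [[FG, OFC], [OFC, FG], [AMY, OFC], [OFC, AMY]]}
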