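{"dark_fine_1":{"ef0":3.6,"ef_ss":0.4,"k":1.2,"noise_cv":0.05,"seed":101},"dark_fine_2":{"ef0":3.1,"ef_ss":0.3,"k":1,"noise_cv":0.05,"seed":102},"dark_fine_3":{"ef0":4.1,"ef_ss":0.5,"k":1.4,"noise_cv":0.05,"seed":103},"light_fine_1":{"ef0":3.9,"ef_ss":0.6,"k":0.9,"noise_cv":0.05,"seed":104},"light_fine_2":{"ef0":2.6,"ef_ss":0.4,"k":1.1,"noise_cv":0.05,"seed":105},"light_fine_3":{"ef0":5.4,"ef_ss":0.7,"k":1.3,"noise_cv":0.05,"seed":106}}
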