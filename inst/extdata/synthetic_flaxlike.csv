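id,population,L001,L002,L003,L004,L005,L006,L007,L008,L009,L010,L011,L012
D1_i001,D1,204/204,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D1_i002,D1,?/?,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/198,132/132,156/156,126/126
D1_i003,D1,206/206,162/162,208/208,180/180,176/176,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D1_i004,D1,208/208,162/162,208/208,180/180,174/174,186/186,218/218,140/140,196/196,160/160,128/128,126/126
D1_i005,D1,204/204,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D1_i006,D1,204/204,164/164,?/?,180/180,174/174,134/134,218/218,138/138,198/198,132/132,156/156,126/126
D1_i007,D1,206/206,162/162,208/208,180/180,176/176,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D1_i008,D1,206/206,162/162,208/208,180/180,172/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D2_i001,D2,206/206,160/160,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D2_i002,D2,206/206,999/999,210/210,180/180,142/142,170/170,218/218,138/138,196/196,122/122,?/?,126/126
D2_i003,D2,156/156,162/162,208/208,192/192,142/142,186/186,218/218,138/138,192/192,132/132,134/134,126/126
D2_i004,D2,206/206,999/999,208/208,194/194,142/142,170/170,218/218,138/138,198/198,132/132,134/134,126/126
D2_i005,D2,156/156,162/162,208/208,194/194,142/142,186/186,216/216,138/138,192/192,132/132,136/136,126/126
D2_i006,D2,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/140,196/196,130/130,156/156,126/126
D2_i007,D2,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,128/128
D2_i008,D2,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,128/128
D3_i001,D3,204/204,999/999,208/208,194/194,174/174,134/170,218/218,138/138,198/198,132/132,134/134,126/126
D3_i002,D3,204/204,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D3_i003,D3,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,128/128
D3_i004,D3,156/156,162/162,208/208,194/194,142/142,186/186,216/216,138/138,192/192,132/132,136/136,126/126
D3_i005,D3,204/204,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D3_i006,D3,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,128/128
D3_i007,D3,206/206,160/160,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D3_i008,D3,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D4_i001,D4,208/208,162/162,164/164,180/180,126/126,186/186,168/168,138/138,198/198,160/160,126/126,132/132
D4_i002,D4,206/206,?/?,164/164,180/180,126/126,186/186,168/168,138/138,198/198,160/160,156/156,126/126
D4_i003,D4,208/208,162/162,164/164,180/180,126/126,186/186,168/168,138/138,198/198,160/160,128/128,132/132
D4_i004,D4,156/156,162/162,164/164,194/194,142/142,136/136,214/214,138/138,196/196,132/132,999/999,126/126
D4_i005,D4,208/208,162/162,164/164,180/180,126/126,186/186,168/168,138/138,198/198,160/160,128/128,132/132
D4_i006,D4,208/208,162/162,164/164,180/180,126/126,186/186,168/168,138/138,198/198,160/160,126/126,132/132
D4_i007,D4,156/156,162/162,208/208,194/194,142/142,186/186,218/218,138/138,192/192,132/132,134/134,126/126
D4_i008,D4,999/999,162/162,210/210,178/178,142/142,186/186,188/188,138/138,198/198,132/132,999/999,126/126
D5_i001,D5,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,999/999,156/156,126/126
D5_i002,D5,206/206,162/162,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,128/128
D5_i003,D5,204/204,162/162,164/164,180/180,174/174,136/136,186/186,138/138,196/196,132/132,154/154,126/126
D5_i004,D5,204/204,162/162,208/208,180/180,174/174,136/136,188/188,138/138,198/198,160/160,128/128,132/132
D5_i005,D5,204/204,162/162,210/210,178/178,142/142,186/186,188/188,140/140,198/198,132/132,999/999,126/126
D5_i006,D5,156/156,162/162,164/164,180/180,128/128,186/186,168/168,138/138,198/198,132/132,134/134,132/132
D5_i007,D5,206/206,162/162,208/208,180/180,176/176,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D5_i008,D5,208/208,162/162,208/208,180/180,174/174,186/186,218/218,140/140,196/196,160/160,128/128,126/126
D6_i001,D6,156/156,162/162,208/208,194/194,142/142,186/186,218/218,138/138,192/192,132/132,134/134,126/126
D6_i002,D6,204/204,?/?,164/164,180/180,174/174,136/136,186/186,138/138,196/196,132/132,154/154,126/126
D6_i003,D6,156/156,162/162,164/164,180/180,174/174,134/134,218/218,138/138,196/196,132/132,?/?,126/126
D6_i004,D6,208/208,?/?,164/164,180/180,126/126,186/186,188/188,138/138,198/198,160/160,156/156,132/132
D6_i005,D6,206/206,160/160,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D6_i006,D6,206/206,160/160,208/208,180/180,174/174,134/134,218/218,138/138,196/196,132/132,156/156,126/126
D6_i007,D6,156/156,162/162,208/208,194/194,142/142,186/186,216/216,138/138,192/192,132/132,136/136,126/126
D6_i008,D6,156/156,162/162,164/164,194/194,142/142,136/136,218/218,138/138,196/196,124/124,134/134,126/126
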