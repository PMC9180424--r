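indicator,n_microblogs,corr_number,sentiment_score,corr_sentiment,topic_index
n_microblogs,1,0.31582,0.166667,0.45225,0.12424
corr_number,3.16636,1,0.65392,1.1,0.16667
sentiment_score,6,1.52924,1,1.27,0.72737
corr_sentiment,2.21116,0.90909,0.7874,1,1.1
topic_index,8.04894,6,1.37482,0.90909,1
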