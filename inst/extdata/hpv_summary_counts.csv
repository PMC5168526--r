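class,n_tweets,n_users,mean_followers,median_followers,n_link,n_hashtag,n_mention,n_prevention,n_side_effects,mean_retweets,median_retweets
positive,75393,36283,8022,459,57800,36638,44558,20425,12921,9.7,1
negative,48940,24010,4772,467,34491,21523,31085,5647,22726,9.1,1
neutral,25110,15045,6093,445,18898,10890,12659,6477,3787,7.8,0
no_mention,43936,25954,6352,381,26870,17915,23747,3209,2619,22.0,0
total,193379,78643,6569,443,138059,86966,112049,35758,42053,12.1,1
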