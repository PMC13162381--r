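source,food_id,name,calories_kcal,protein_g,fiber_g,calcium_mg,phosphorus_mg,potassium_mg,sodium_mg
USDA,U001,white rice cooked,130,2.7,0.4,10,43,35,1
USDA,U002,brown rice cooked,112,2.3,1.8,10,83,79,5
USDA,U003,oatmeal cooked,71,2.5,1.7,9,77,70,4
USDA,U004,white bread,265,9.0,2.7,144,99,126,491
USDA,U005,whole wheat bread,247,13.0,6.8,107,229,254,450
USDA,U006,flour tortilla,306,8.2,3.3,146,129,125,736
USDA,U007,corn tortilla,218,5.7,6.3,81,314,186,45
USDA,U008,chicken breast roasted,165,31.0,0,15,228,256,74
USDA,U009,ground beef cooked,250,26.0,0,18,198,318,76
USDA,U010,pork loin cooked,242,27.0,0,19,246,423,62
USDA,U011,salmon cooked,206,22.0,0,15,252,384,61
USDA,U012,tilapia cooked,128,26.0,0,14,204,380,56
USDA,U013,canned tuna in water,116,26.0,0,14,217,237,247
USDA,U014,egg hard boiled,155,13.0,0,50,172,126,124
USDA,U015,tofu firm,76,8.0,0.3,350,97,121,7
USDA,U016,black beans cooked,132,8.9,8.7,27,140,355,1
USDA,U017,chickpeas cooked,164,8.9,7.6,49,168,291,7
USDA,U018,lentils cooked,116,9.0,7.9,19,180,369,2
USDA,U019,peanut butter,588,25.0,6.0,49,335,649,459
USDA,U020,almonds,579,21.0,12.5,269,481,733,1
USDA,U021,apple raw,52,0.3,2.4,6,11,107,1
USDA,U022,banana raw,89,1.1,2.6,5,22,358,1
USDA,U023,orange raw,47,0.9,2.4,40,14,181,0
USDA,U024,grapes raw,69,0.7,0.9,10,20,191,2
USDA,U025,strawberries raw,32,0.7,2.0,16,24,153,1
USDA,U026,blueberries raw,57,0.7,2.4,6,12,77,1
USDA,U027,pineapple raw,50,0.5,1.4,13,8,109,1
USDA,U028,carrots raw,41,0.9,2.8,33,35,320,69
USDA,U029,broccoli cooked,35,2.4,3.3,40,67,293,41
USDA,U030,green beans cooked,35,1.9,3.2,44,29,146,1
USDA,U031,cabbage raw,25,1.3,2.5,40,26,170,18
USDA,U032,cucumber,15,0.7,0.5,16,24,147,2
USDA,U033,red bell pepper raw,31,1.0,2.1,7,26,211,4
USDA,U034,onion raw,40,1.1,1.7,23,29,146,4
USDA,U035,potato boiled,87,1.9,1.8,5,44,379,4
USDA,U036,sweet potato baked,90,2.0,3.3,38,54,475,36
USDA,U037,zucchini cooked,15,1.1,1.0,18,37,264,3
USDA,U038,cauliflower cooked,23,1.8,2.3,16,32,142,15
USDA,U039,applesauce unsweetened,42,0.2,1.1,4,7,75,2
USDA,U040,olive oil,884,0,0,1,0,1,2
USDA,U041,butter unsalted,717,0.9,0,24,24,24,11
USDA,U042,cream cheese,342,6.0,0,98,107,138,321
MW,M001,porridge oats,363,11.0,9.0,54,380,350,9
MW,M002,baked beans in tomato sauce,84,4.8,3.7,45,89,296,422
MW,M003,cheddar cheese,416,25.0,0,739,505,76,723
MW,M004,white fish fillet steamed,96,21.0,0,22,190,340,90
MW,M005,digestive biscuit,471,6.5,3.5,92,130,160,600
MW,M006,english muffin,227,9.9,3.1,160,100,120,420
MW,M007,semi skimmed milk,50,3.6,0,124,96,156,43
MW,M008,greek style yogurt,97,9.0,0,110,135,141,36
MW,M009,cucumber,14,0.7,0.6,18,21,150,3
MW,M010,white rice cooked,131,2.6,0.1,4,34,26,2
AUSNUT,A001,lamb chop grilled,260,25.0,0,8,190,300,70
AUSNUT,A002,kangaroo fillet grilled,98,22.0,0,6,205,350,45
AUSNUT,A003,wheat biscuit cereal,355,12.0,11.0,33,330,340,270
AUSNUT,A004,pumpkin cooked,36,1.2,1.5,18,32,200,1
AUSNUT,A005,green peas cooked,72,4.6,5.2,22,82,150,2
AUSNUT,A006,barramundi cooked,108,21.0,0,25,200,340,60
AUSNUT,A007,multigrain bread,252,9.8,5.2,60,150,180,380
AUSNUT,A008,rockmelon raw,34,0.8,0.9,9,15,267,9
AUSNUT,A009,white rice cooked,129,2.8,0.5,8,40,30,3
AUSNUT,A010,banana raw,90,1.4,2.6,6,24,350,1
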